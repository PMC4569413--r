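#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sweeps over a {0,1} Ising model:
//   P(x) propto exp(sum_i tau_i x_i + sum_{i<j} omega_ij x_i x_j),
//   P(x_i = 1 | rest) = logistic(tau_i + sum_j omega_ij x_j).
// Sites are updated in index order; one row is emitted every `thin` sweeps
// after `burn_in` sweeps. Uses R's RNG so set.seed() controls the draw.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericVector tau, NumericMatrix omega,
                               int n, int burn_in, int thin) {
  const int p = tau.size();
  IntegerMatrix out(n, p);
  std::vector<double> x(p);
  for (int j = 0; j < p; ++j) x[j] = (unif_rand() < 0.5) ? 1.0 : 0.0;
  const int total = burn_in + n * thin;
  int row = 0;
  for (int s = 0; s < total; ++s) {
    for (int i = 0; i < p; ++i) {
      double eta = tau[i];
      for (int j = 0; j < p; ++j) {
        if (j != i) eta += omega(j, i) * x[j];
      }
      const double pr = 1.0 / (1.0 + std::exp(-eta));
      x[i] = (unif_rand() < pr) ? 1.0 : 0.0;
    }
    if (s >= burn_in && ((s - burn_in + 1) % thin == 0)) {
      for (int j = 0; j < p; ++j) out(row, j) = static_cast<int>(x[j]);
      ++row;
    }
  }
  return out;
}
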