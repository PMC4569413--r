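# Independent oracles used by the tests. These deliberately avoid the code
# paths of the package (and of glmnet/igraph) so that agreement is evidence,
# not tautology.

# Exact probability of every binary state under the {0,1} Ising model
# P(x) propto exp(sum tau_i x_i + sum_{i<j} omega_ij x_i x_j), by full
# enumeration of the 2^p states. Rows of $states follow binary counting
# order (x1 flips fastest).
enumerate_ising <- function(tau, omega) {
  p <- length(tau)
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  colnames(states) <- NULL
  logw <- apply(states, 1, function(x) {
    sum(tau * x) + sum(omega[upper.tri(omega)] *
                         (outer(x, x)[upper.tri(omega)]))
  })
  w <- exp(logw - max(logw))
  list(states = states, prob = w / sum(w))
}

# Empirical distribution of sampled rows over the enumerated states.
empirical_state_probs <- function(values, states) {
  keys <- apply(states, 1, paste, collapse = "")
  obs <- table(factor(apply(values, 1, paste, collapse = ""), levels = keys))
  as.numeric(obs) / nrow(values)
}

total_variation <- function(p, q) sum(abs(p - q)) / 2

# l1-penalized logistic regression by proximal gradient (FISTA) with an
# unpenalized intercept: minimizes (1/n) negloglik + lambda * sum(abs(beta)).
# Independent of glmnet's coordinate descent.
fista_logistic <- function(y, X, lambda, max_iter = 20000, tol = 1e-10) {
  X1 <- cbind(1, X)
  n <- nrow(X1); d <- ncol(X1)
  L <- max(eigen(crossprod(X1) / (4 * n), symmetric = TRUE,
                 only.values = TRUE)$values)
  beta <- z <- numeric(d)
  tk <- 1
  grad <- function(b) {
    mu <- 1 / (1 + exp(-(X1 %*% b)))
    crossprod(X1, mu - y) / n
  }
  for (it in seq_len(max_iter)) {
    g <- grad(z)
    bnew <- z - as.numeric(g) / L
    bnew[-1] <- sign(bnew[-1]) * pmax(abs(bnew[-1]) - lambda / L, 0)
    tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    znew <- bnew + ((tk - 1) / tnew) * (bnew - beta)
    if (max(abs(bnew - beta)) < tol && it > 1) {
      beta <- bnew
      break
    }
    beta <- bnew; z <- znew; tk <- tnew
  }
  list(intercept = beta[1], coefficients = beta[-1])
}

penalized_objective <- function(y, X, intercept, coefficients, lambda) {
  eta <- intercept + as.numeric(as.matrix(X) %*% coefficients)
  nll <- -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) / length(y)
  nll + lambda * sum(abs(coefficients))
}

# EBIC-minimizing path index computed entirely with the FISTA oracle:
# refits the penalized problem independently at every path lambda,
# evaluates the unpenalized log-likelihood at the solution, and picks the
# minimizer (ties toward the larger lambda, i.e. the first index). Supports
# are read with a small threshold because FISTA produces exact zeros only
# via soft-thresholding.
oracle_choose_lambda <- function(y, X, path, gamma, p_total) {
  n <- length(y)
  ebics <- vapply(path, function(lam) {
    fit <- fista_logistic(y, X, lam)
    co <- fit$coefficients
    co[abs(co) < 1e-6] <- 0
    k <- sum(co != 0)
    eta <- fit$intercept + as.numeric(X %*% co)
    ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    -2 * ll + k * log(n) + 2 * gamma * k * log(p_total - 1)
  }, numeric(1))
  which.min(ebics)
}

# --- graph oracles ------------------------------------------------------

# Connectivity by union-find.
union_find_connected <- function(adj) {
  p <- nrow(adj)
  if (p == 0) return(TRUE)
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j && adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(p), find, integer(1)))) == 1
}

# Triangle / triple enumeration for all three clustering conventions.
brute_clustering <- function(adj, convention) {
  p <- nrow(adj)
  deg <- rowSums(adj)
  tri <- numeric(p)
  for (i in seq_len(p)) {
    nb <- which(adj[i, ])
    if (length(nb) >= 2) {
      pairs <- utils::combn(nb, 2)
      tri[i] <- sum(adj[cbind(pairs[1, ], pairs[2, ])])
    }
  }
  local <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), NA)
  switch(convention,
         average_local_zero = mean(ifelse(is.na(local), 0, local)),
         average_local_exclude =
           if (all(is.na(local))) 0 else mean(local, na.rm = TRUE),
         transitivity = {
           triples <- sum(deg * (deg - 1) / 2)
           if (triples == 0) 0 else sum(tri) / triples
         })
}

# All-pairs shortest paths by Floyd-Warshall.
floyd_warshall_aspl <- function(adj) {
  p <- nrow(adj)
  d <- matrix(Inf, p, p)
  d[adj] <- 1
  diag(d) <- 0
  for (k in seq_len(p)) for (i in seq_len(p)) for (j in seq_len(p)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  mean(d[upper.tri(d)])
}

# Random symmetric adjacency with given edge probability.
random_adjacency <- function(p, prob) {
  adj <- matrix(FALSE, p, p)
  adj[upper.tri(adj)] <- stats::runif(p * (p - 1) / 2) < prob
  adj | t(adj)
}

adj_to_network <- function(adj, weights = NULL) {
  p <- nrow(adj)
  W <- matrix(0, p, p)
  if (is.null(weights)) weights <- 1
  W[adj] <- weights
  W <- (W + t(W)) / 2
  W[!(adj | t(adj))] <- 0
  diag(W) <- 0
  symptomnet::symptom_network((W + t(W)) / 2, paste0("v", seq_len(p)))
}

# --- small fixtures -----------------------------------------------------

# A two-diagnosis toy catalog: diagnosis A (screener A_1 gating A_2, A_3),
# diagnosis B with no screeners.
toy_catalog <- function() {
  symptomnet::symptom_catalog(data.frame(
    symptom_id = c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3"),
    diagnosis_code = rep(c("A", "B"), each = 3),
    within_diagnosis_number = rep(1:3, 2),
    criterion_label = paste0("c", 1:6),
    is_screener = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    timeframe = "past3y", stringsAsFactors = FALSE))
}

# The two-block recovery design: two blocks of 5 symptoms, every
# within-block pair coupled at `within`, no between couplings, thresholds
# `tau`.
two_block_params <- function(within = 1, tau = -1) {
  blocks <- rep(c("P", "Q"), each = 5)
  p <- 10
  omega <- matrix(0, p, p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    if (blocks[i] == blocks[j]) omega[i, j] <- omega[j, i] <- within
  }
  ids <- paste0(blocks, "_", rep(1:5, 2))
  dimnames(omega) <- list(ids, ids)
  symptomnet::ising_parameters(rep(tau, p), omega)
}

two_block_catalog <- function() {
  symptomnet::symptom_catalog(data.frame(
    symptom_id = paste0(rep(c("P", "Q"), each = 5), "_", rep(1:5, 2)),
    diagnosis_code = rep(c("P", "Q"), each = 5),
    within_diagnosis_number = rep(1:5, 2),
    criterion_label = "c", is_screener = FALSE, timeframe = "past3y",
    stringsAsFactors = FALSE))
}
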