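---
title: "Estimating symptom networks from binary survey data: model, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating symptom networks from binary survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

`symptomnet` treats a set of p binary psychiatric symptoms as nodes of a
pairwise Markov random field (an Ising model in the \{0,1\}
parameterization). The joint distribution is

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} \Omega_{ij} x_i x_j\Big),
\qquad x \in \{0,1\}^p,$$

with thresholds $\tau_i$ (item main effects; a very negative $\tau_i$ makes
symptom $i$ rare) and symmetric couplings $\Omega_{ij}$ (conditional
associations on the logit scale). The \{0,1\} coding, rather than ±1, is
deliberate: it matches presence/absence data, and it makes the full
conditional of each node exactly a logistic regression on the other nodes,

$$P(x_i = 1 \mid x_{-i}) = \mathrm{logit}^{-1}\Big(\tau_i + \sum_{j \ne i}
\Omega_{ij} x_j\Big),$$

so estimated regression coefficients live on the same scale as simulated
couplings and can be compared directly.

## The estimator

`estimate_network()` is the nodewise "eLasso" scheme:

1. **Per-node l1-penalized logistic regression.** Each symptom is regressed
   on all p − 1 others, minimizing
   $\tfrac1n \cdot \text{negative log-likelihood} + \lambda \sum_j |\beta_j|$
   with an unpenalized intercept (thresholds are nuisance main effects, not
   edges). Predictors are left unstandardized: they are already on a common
   0/1 scale, and standardizing would silently reweight the penalty by item
   prevalence. The fits are solved by coordinate descent (`glmnet`); a small
   internal Newton/soft-threshold solver covers the single-predictor case.
2. **A penalty path per node.** `lambda_path()` starts at
   $\lambda_{max} = \max_j |x_j^\top (y - \bar y)| / n$ — the exact
   Karush-Kuhn-Tucker boundary below which the first predictor enters — and
   descends log-linearly to `lambda_min_ratio` · $\lambda_{max}$. Defaults
   (`n_lambda = 100`, `lambda_min_ratio = 0.01`) follow common l1-path
   practice; both are configurable. Coefficients whose magnitude is below
   1e−10 are treated as exact zeros, so the boundary model at
   $\lambda_{max}$ has zero neighbors by construction.
3. **EBIC model selection.** Every path model is scored with the extended
   Bayesian information criterion
   $\mathrm{EBIC} = -2\ell + k\ln n + 2\gamma k \ln(p-1)$, where $k$ counts
   nonzero neighbor coefficients and $\ell$ is the *unpenalized*
   log-likelihood evaluated at the *penalized* coefficients (an unpenalized
   refit on the selected support is available via
   `estimation_config(refit = TRUE)` but is not the default, matching the
   published convention of this estimator family). Ties are broken toward
   the larger penalty, i.e. the sparser model, so selection is
   deterministic. The default $\gamma = 0.25$ is the standard compromise:
   $\gamma = 0$ is ordinary BIC, larger $\gamma$ buys extra protection
   against false edges in wide problems.
4. **Symmetrization.** The nodewise coefficients form a directed matrix B.
   Under the default AND rule an edge (i, j) is kept only when both
   $B_{ij}$ and $B_{ji}$ are nonzero (OR keeps either); the retained weight
   is the average $(B_{ij} + B_{ji})/2$. AND is the conservative choice and
   its support is provably contained in OR's on the same fits (this is
   tested).

Columns that are constant (a symptom nobody or everybody endorses) make the
nodewise regression degenerate; `estimate_network()` refuses to run and
names every offending column. This mirrors what happens to real screener
items in subsamples selected for positive screens, where 100% prevalence
makes the network inestimable.

## The synthetic-data generator

Because the survey data this methodology is typically applied to are
restricted-access, the package carries a first-class simulator so every
pipeline stage is testable end to end.

* `default_catalog()` encodes a 120-symptom roster over 12 diagnoses
  (sizes 17, 10, 10, 8, 5, 5, 4, 4, 19, 18, 13, 7), with screeners for
  every diagnosis except ADHD and two screeners for the depressive-episode
  section (low mood, loss of interest). Criterion labels are placeholders
  where no transcription exists; all computations depend only on sizes and
  screener structure.
* `make_block_parameters()` draws a block-structured Ising model: each
  within-diagnosis pair gets a coupling with probability `within_density`
  (default 0.6), each between-diagnosis pair with probability
  `between_density` (default 0.02); coupling values are uniform on
  `within_weight_range` (default \[0.2, 0.6\]) and `between_weight_range`
  (default \[0.1, 0.3\]), thresholds uniform on \[−3, −1.5\]. These defaults
  were chosen once so that simulated prevalences at n = 2000 span roughly
  5–90% with no constant columns — survey-like rare-to-common symptoms —
  while keeping the segregated cluster structure the method is meant to
  recover. Stronger within couplings with these block sizes push blocks
  into all-on saturation, which no real symptom inventory shows.
* `gibbs_sample()` draws respondents by single-site Gibbs sweeps
  (sequential site order, default 1000 burn-in sweeps, keep every 10th; the
  sampler core is C++). For p ≤ 3 the sampled distribution is checked
  against exact enumeration of the state space (total-variation distance
  below 0.02 at 50,000 draws).
* `apply_skip_logic()` reproduces the structured missingness of a screened
  diagnostic interview: when a respondent's screeners for a diagnosis are
  all 0 (the default "all" gate; "any" is available because multi-screener
  sections could plausibly gate either way), the diagnosis's remaining
  items were never asked and become explicitly missing. Missingness is a
  real third state in storage — never silently 0 — so that
  `impute_skip_zeros()`, the zero-imputation the survey coding applies, is
  a separate, auditable step. `filter_rows_by_missingness()` implements the
  strict "less than" threshold used for sensitivity subsampling; fully
  observed rows are always retained, so a threshold of 0 selects exactly
  the complete cases.

What the simulator does *not* emulate: survey weights and sampling design,
demographic covariates, item wording effects, and any marginal-prevalence
calibration to a particular survey (screener prevalences are free
parameters). Passing tests on simulated data therefore demonstrate that the
estimator recovers the structure of data generated by the model it assumes
— not that any particular empirical network is correct.

## Graph descriptives

Metrics run on the *binarized* graph: a connection is any nonzero weight,
positive or negative, and path lengths are hop counts. Three clustering
conventions are first-class (`average_local_zero`, `average_local_exclude`,
`transitivity`) because a single printed "clustering coefficient" does not
identify its estimator; reports print all three so a reference value can be
matched rather than assumed. `average_shortest_path_length()` errors on
disconnected graphs by default (an average over infinite distances is
meaningless) with an explicit largest-component fallback that warns.

The block-level summary (`summarize_blocks()`) counts realized edges within
each diagnosis and between each diagnosis pair against the potential counts
$n_d(n_d-1)/2$ and $n_{d_1} n_{d_2}$. The per-diagnosis "all other
diagnoses" aggregate uses the denominator $n_d \cdot p$ — the convention of
the published table this output mirrors (its printed aggregate denominators
are each diagnosis's size times 120, not the sum of its between-pair
denominators). Display percentages are rounded half *up* to one decimal
(6.875 → 6.9), matching the printed cells; stored percentages keep full
precision.

## Numerical and design choices

* **Determinism.** Every stochastic stage (parameter draw, Gibbs sampler,
  edge placement, layout) takes an explicit integer seed; the whole
  simulate → skip → impute → estimate pipeline is bit-reproducible at a
  fixed seed. The estimator itself is deterministic given data and config.
* **EBIC vs refit.** Evaluating the unpenalized likelihood at the shrunken
  coefficients (default) slightly favors sparser models relative to a
  support refit; both are exposed, and the default's penalty choice is
  verified against an independent proximal-gradient refit oracle at every
  path point on small designs.
* **Problem sizes in the tests.** The test and acceptance runs use
  n = 2000–5000 and p = 3–120: large enough that EBIC selection is stable
  (two-block recovery reaches mean sensitivity ≥ 0.9 with false-positive
  rate ≤ 0.1 across 20 seeded replicates; independent columns yield under
  one false edge per run), small enough to run on one CPU in minutes.
  At these sizes an estimated 120-node network is typically sparser — and
  sometimes disconnected — compared with an estimate from a survey-scale
  sample tens of times larger; the descriptive reports handle both.
* **Degenerate inputs.** Constant columns, disconnected graphs, asymmetric
  weight matrices, nonzero diagonals and malformed catalogs all fail loudly
  with the offending item named; readers never coerce.

## A surrogate for the published weight matrix

The package ships the published block-count table
(`published_table1_counts()`) as a plain-text input and can generate a
*synthetic* surrogate network realizing those counts exactly
(`synthetic_table1_network()`), with uniform-random edge placement inside
each block. Block-level quantities computed from it — node count,
per-block percentages, diagnosis-partner counts, connectedness — are
faithful by construction. Hop-level descriptives (clustering, average
shortest path length) depend on the placement and are reported as
properties of the surrogate, not of the original network; interestingly,
the block counts alone nearly determine them, as the acceptance report
shows.

## Known limitations

* The estimator assumes complete data after zero-imputation; the imputation
  itself biases within-diagnosis associations upward and between-diagnosis
  associations downward for gated items, which is why the simulator makes
  the skip step explicit and why sensitivity filtering is provided.
* Cross-sectional, undirected estimation only: no temporal or directed
  structure.
* No survey weights or covariate adjustment.
* Exact replication of any published weight matrix from raw data is out of
  reach by design (the raw survey is restricted); the package instead
  validates the machinery on simulated ground truth and the published
  block counts.
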