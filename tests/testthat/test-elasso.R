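# small simulated design shared across estimation tests
.sim_data <- function(n, seed, params) {
  gibbs_sample(params, n, burn_in = 200, thin = 2, seed = seed)
}

test_that("lambda path spans lambda_max down to the stated ratio", {
  set.seed(21)
  X <- matrix(rbinom(200 * 4, 1, 0.4), 200, 4)
  y <- rbinom(200, 1, plogis(-0.5 + X[, 1]))
  cfg <- estimation_config(n_lambda = 25, lambda_min_ratio = 0.05)
  path <- lambda_path(y, X, cfg)
  expect_length(path, 25)
  expect_true(all(diff(path) < 0))
  expect_equal(path[25] / path[1], 0.05, tolerance = 1e-10)
  # single-point path is lambda_max itself
  lmax <- lambda_path(y, X, estimation_config(n_lambda = 1))
  expect_equal(lmax, max(abs(crossprod(X, y - mean(y)))) / length(y))
  # the fit at lambda_max keeps no predictors
  at_max <- fit_penalized_logistic(y, X, lmax, cfg)
  expect_true(all(at_max$coefficients == 0))
  expect_error(lambda_path(rep(1, 200), X, cfg), "constant")
})

test_that("penalized fits minimize the stated objective", {
  set.seed(22)
  X <- matrix(rbinom(300 * 3, 1, 0.5), 300, 3)
  y <- rbinom(300, 1, plogis(-0.3 + 0.8 * X[, 1] - 0.6 * X[, 2]))
  cfg <- estimation_config()
  for (lam in c(0.001, 0.01, 0.05)) {
    fit <- fit_penalized_logistic(y, X, lam, cfg)
    oracle <- fista_logistic(y, X, lam)
    # both reach the same objective value (same minimizer up to tolerance)
    expect_equal(
      penalized_objective(y, X, fit$intercept, fit$coefficients, lam),
      penalized_objective(y, X, oracle$intercept, oracle$coefficients, lam),
      tolerance = 1e-6)
  }
  # fully shrunk model: intercept collapses to logit of the base rate
  big <- fit_penalized_logistic(y, X, 10, cfg)
  expect_true(all(big$coefficients == 0))
  expect_equal(big$intercept, qlogis(mean(y)), tolerance = 1e-6)
})

test_that("unpenalized single-predictor fit matches glm", {
  set.seed(23)
  x <- rbinom(400, 1, 0.5)
  y <- rbinom(400, 1, plogis(-0.4 + 0.9 * x))
  fit <- fit_penalized_logistic(y, matrix(x, ncol = 1), 1e-12,
                                estimation_config(convergence_tol = 1e-12))
  ref <- glm(y ~ x, family = binomial())
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-4)
  expect_equal(fit$coefficients, unname(coef(ref)[2]), tolerance = 1e-4)
})

test_that("duplicated predictors split weight without changing the objective", {
  set.seed(24)
  x <- rbinom(500, 1, 0.5)
  y <- rbinom(500, 1, plogis(-0.2 + x))
  lam <- 0.02
  single <- fit_penalized_logistic(y, matrix(x, ncol = 1), lam,
                                   estimation_config())
  dup <- fit_penalized_logistic(y, cbind(x, x), lam, estimation_config())
  expect_lte(sum(abs(dup$coefficients)),
             2 * abs(single$coefficients) + 1e-8)
  expect_equal(
    penalized_objective(y, cbind(x, x), dup$intercept, dup$coefficients, lam),
    penalized_objective(y, matrix(x, ncol = 1), single$intercept,
                        single$coefficients, lam),
    tolerance = 1e-6)
})

test_that("EBIC formula is exact and reduces to BIC at gamma 0", {
  expect_equal(ebic_score(-100, 0, 50, 10, 0.25), 200)
  expect_equal(ebic_score(-100, 0, 5000, 120, 2), 200)
  expect_equal(ebic_score(-50, 2, 100, 10, 0.25),
               100 + 2 * log(100) + 2 * 0.25 * 2 * log(9))
  expect_equal(ebic_score(-50, 3, 200, 15, 0),
               100 + 3 * log(200))
  expect_error(ebic_score(-50, 1, 100, 1, 0.25), "at least 2")
})

test_that("fit_node keeps no neighbors for an independent node", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    v <- matrix(rbinom(2000 * 5, 1, 0.3), 2000, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
    fit_node(binary_dataset(v), 1)$chosen_k
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.2)
})

test_that("fit_node's EBIC choice matches the independent refit oracle", {
  cfg <- estimation_config(n_lambda = 25)
  prm <- two_block_params()
  # 4-symptom chain as in the small oracle design
  om <- matrix(0, 4, 4)
  om[1, 2] <- om[2, 3] <- om[3, 4] <- 1
  om <- om + t(om)
  chain <- ising_parameters(rep(-0.5, 4), om)
  for (s in 1:5) {
    d <- .sim_data(2000, seed = 30 + s, params = chain)
    for (node in 1:4) {
      y <- as.numeric(d$values[, node])
      X <- d$values[, -node, drop = FALSE]; storage.mode(X) <- "double"
      res <- fit_node(d, node, cfg)
      oracle_idx <- oracle_choose_lambda(y, X, lambda_path(y, X, cfg),
                                         cfg$gamma, ncol(d$values))
      expect_identical(res$chosen_index, oracle_idx)
    }
  }
})

test_that("fit_node names degenerate columns and chosen_k is consistent", {
  v <- cbind(a = rep(1L, 50), b = rbinom(50, 1, 0.5))
  v[1, 2] <- 1L; v[2, 2] <- 0L
  expect_error(fit_node(binary_dataset(v), 1), "'a'")
  prm <- two_block_params()
  d <- .sim_data(800, seed = 40, params = prm)
  res <- fit_node(d, 3)
  expect_identical(res$chosen_k, sum(res$neighbor_coefficients != 0))
  # refit variant: EBIC from an unpenalized refit on the support can only
  # improve the likelihood term, so its chosen model is no sparser
  res_refit <- fit_node(d, 3, estimation_config(refit = TRUE))
  expect_gte(res_refit$chosen_k, res$chosen_k)
  expect_identical(res_refit$chosen_k,
                   sum(res_refit$neighbor_coefficients != 0))
})

test_that("assemble_network applies the AND/OR rules and averaging", {
  mk <- function(B) {
    ids <- paste0("v", seq_len(nrow(B)))
    lapply(seq_len(nrow(B)), function(i) {
      co <- B[i, -i]
      names(co) <- ids[-i]
      structure(list(node = i, node_id = ids[i], intercept = 0,
                     neighbor_coefficients = co, chosen_lambda = 1,
                     chosen_index = 1L, chosen_k = sum(co != 0),
                     ebic_at_chosen = 0), class = "nodewise_result")
    })
  }
  B <- matrix(0, 3, 3)
  B[1, 2] <- 0.6           # one-sided
  B[2, 3] <- 0.5; B[3, 2] <- 0.3   # two-sided
  res <- mk(B)
  W_and <- assemble_network(res, estimation_config(rule = "AND"))$weights
  W_or <- assemble_network(res, estimation_config(rule = "OR"))$weights
  expect_equal(W_and["v1", "v2"], 0)
  expect_equal(W_or["v1", "v2"], 0.3)
  expect_equal(W_and["v2", "v3"], 0.4)
  expect_equal(W_or["v2", "v3"], 0.4)
  # property: symmetry and support containment over random sparse B
  for (s in 1:20) {
    set.seed(s)
    p <- sample(3:8, 1)
    B <- matrix(rbinom(p * p, 1, 0.3) * rnorm(p * p), p, p)
    diag(B) <- 0
    res <- mk(B)
    for (rule in c("AND", "OR")) {
      W <- assemble_network(res, estimation_config(rule = rule))$weights
      expect_equal(W, t(W))
      expect_true(all(W[B == 0 & t(B) == 0] == 0))
      if (rule == "AND") W_and_s <- W else {
        expect_true(all(W[W_and_s != 0] != 0))  # AND support inside OR
      }
    }
  }
})

test_that("estimate_network recovers a two-block design and is equivariant", {
  prm <- two_block_params()
  d <- .sim_data(3000, seed = 50, params = prm)
  net <- estimate_network(d)
  truth <- prm$couplings != 0
  found <- net$weights != 0
  # recovered within-block weights are positive
  expect_true(all(net$weights[found & truth] > 0))
  # decent recovery on one replicate (full check in the acceptance suite)
  expect_gt(sum(found & truth) / sum(truth[upper.tri(truth)]) / 2, 0.6)

  # permutation equivariance
  perm <- sample(ncol(d$values))
  dp <- binary_dataset(d$values[, perm])
  netp <- estimate_network(dp)
  unperm <- netp$weights[colnames(d$values), colnames(d$values)]
  # same support exactly; weights agree to solver tolerance
  expect_identical(unperm != 0, net$weights != 0)
  expect_equal(unperm, net$weights, tolerance = 1e-3)

  # gamma-monotonicity of per-node model size
  ks <- sapply(c(0, 0.25, 0.5, 1), function(g) {
    sapply(1:10, function(i) {
      fit_node(d, i, estimation_config(gamma = g))$chosen_k
    })
  })
  expect_true(all(diff(t(ks)) <= 0))

  # degenerate columns are all reported before aborting
  v <- d$values; v[, 2] <- 1L; v[, 7] <- 0L
  err <- tryCatch(estimate_network(binary_dataset(v)), error = conditionMessage)
  expect_match(err, colnames(v)[2])
  expect_match(err, colnames(v)[7])
})
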