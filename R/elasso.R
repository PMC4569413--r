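#' Estimation settings for the nodewise Ising fit
#'
#' @param gamma EBIC hyperparameter (>= 0); 0 reduces EBIC to BIC. The
#'   default 0.25 is the convention of published nodewise Ising estimators.
#' @param rule edge-retention rule combining the two directed coefficients
#'   of a pair: `"AND"` (both nonzero, default) or `"OR"` (either nonzero).
#' @param n_lambda number of penalty values on the path (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of the largest
#'   (default 0.01), in (0, 1).
#' @param convergence_tol solver convergence tolerance.
#' @param max_iter solver iteration cap.
#' @param refit if `TRUE`, the log-likelihood entering EBIC is taken from an
#'   unpenalized refit on the selected support instead of being evaluated at
#'   the penalized coefficients (default `FALSE`).
#' @return Object of class `estimation_config`.
#' @export
estimation_config <- function(gamma = 0.25, rule = c("AND", "OR"),
                              n_lambda = 100L, lambda_min_ratio = 0.01,
                              convergence_tol = 1e-8, max_iter = 1e5,
                              refit = FALSE) {
  rule <- match.arg(rule)
  if (gamma < 0) stop("gamma must be nonnegative", call. = FALSE)
  if (n_lambda < 1L) stop("n_lambda must be positive", call. = FALSE)
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1) {
    stop("lambda_min_ratio must be in (0, 1)", call. = FALSE)
  }
  if (convergence_tol <= 0 || max_iter <= 0) {
    stop("convergence_tol and max_iter must be positive", call. = FALSE)
  }
  structure(list(gamma = gamma, rule = rule, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter), refit = isTRUE(refit)),
            class = "estimation_config")
}

#' Penalty path for one nodewise regression
#'
#' Log-spaced decreasing sequence from `lambda_max` — the smallest penalty
#' at which the l1-penalized logistic fit keeps no predictors, computed from
#' the maximal absolute score of the intercept-only model,
#' `max_j |x_j' (y - mean(y))| / n` — down to
#' `lambda_max * lambda_min_ratio`.
#'
#' @param y binary response vector (both classes present).
#' @param X predictor matrix (the other symptom columns).
#' @param config an [estimation_config()].
#' @return Strictly decreasing positive numeric vector of length
#'   `config$n_lambda` (length 1 gives `lambda_max` itself).
#' @export
lambda_path <- function(y, X, config = estimation_config()) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: response is constant", call. = FALSE)
  }
  X <- as.matrix(X)
  n <- length(y)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  if (config$n_lambda == 1L) return(lambda_max)
  exp(seq(log(lambda_max), log(lambda_max * config$lambda_min_ratio),
          length.out = config$n_lambda))
}

#' Fit one l1-penalized logistic regression
#'
#' Minimizes `(1/n) * negative Bernoulli log-likelihood + lambda * sum|beta|`
#' with an unpenalized intercept. Columns are not standardized, so the
#' penalty applies to the raw 0/1 predictors and coefficients stay on the
#' logit scale of the Ising couplings.
#'
#' @param y binary response (both classes present).
#' @param X predictor matrix.
#' @param lambda positive penalty.
#' @param config an [estimation_config()].
#' @return List with `intercept` and `coefficients` (length `ncol(X)`).
#' @export
fit_penalized_logistic <- function(y, X, lambda,
                                   config = estimation_config()) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: response is constant", call. = FALSE)
  }
  if (ncol(X) >= 2L) {
    path <- sort(unique(c(lambda_path(y, X, config), lambda)),
                 decreasing = TRUE)
    fit <- .glmnet_path(y, X, path, config)
    co <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = TRUE,
                                         x = X, y = y))
  } else {
    co <- .prox_newton_1d(y, X, lambda, config)
  }
  co[-1][abs(co[-1]) < 1e-10] <- 0  # boundary solutions are exact zeros
  list(intercept = co[1], coefficients = co[-1])
}

# glmnet over a fixed path; shared by fit_penalized_logistic and fit_node.
.glmnet_path <- function(y, X, path, config) {
  glmnet::glmnet(X, y, family = "binomial", alpha = 1, lambda = path,
                 standardize = FALSE, thresh = config$convergence_tol,
                 maxit = config$max_iter)
}

# Penalized logistic fit with a single predictor (glmnet needs >= 2
# columns): cyclic Newton step on the intercept plus a soft-thresholded
# quadratic-approximation step on the slope.
.prox_newton_1d <- function(y, X, lambda, config) {
  x <- as.numeric(X[, 1]); n <- length(y)
  b0 <- stats::qlogis(mean(y)); b1 <- 0
  for (it in seq_len(config$max_iter)) {
    old <- c(b0, b1)
    mu <- stats::plogis(b0 + b1 * x)
    w <- pmax(mu * (1 - mu), 1e-10)
    b0 <- b0 + sum(y - mu) / sum(w)
    mu <- stats::plogis(b0 + b1 * x)
    w <- pmax(mu * (1 - mu), 1e-10)
    num <- sum(x * (y - mu)) / n + b1 * sum(w * x^2) / n
    den <- sum(w * x^2) / n
    b1 <- sign(num) * max(abs(num) - lambda, 0) / den
    if (max(abs(c(b0, b1) - old)) < config$convergence_tol) {
      return(c(b0, b1))
    }
  }
  stop("penalized logistic fit did not converge in ", config$max_iter,
       " iterations (lambda = ", signif(lambda, 4), ")", call. = FALSE)
}

#' Extended BIC of one nodewise model
#'
#' `EBIC = -2 * loglik + k * log(n) + 2 * gamma * k * log(p - 1)`, where `k`
#' counts the nonzero neighbor coefficients and `p - 1` is the number of
#' candidate neighbors. `gamma = 0` recovers the ordinary BIC.
#'
#' @param loglik unpenalized Bernoulli log-likelihood evaluated at the
#'   penalized solution (or at the refit, see [estimation_config()]).
#' @param k number of nonzero neighbor coefficients.
#' @param n sample size.
#' @param p total number of symptoms (>= 2).
#' @param gamma EBIC hyperparameter.
#' @return EBIC value (smaller is better).
#' @export
ebic_score <- function(loglik, k, n, p, gamma) {
  if (p < 2) stop("p must be at least 2", call. = FALSE)
  -2 * loglik + k * log(n) + 2 * gamma * k * log(p - 1)
}

# Unpenalized Bernoulli log-likelihood at linear predictor eta
# (overflow-safe form of sum(y*eta - log(1 + exp(eta)))).
.bernoulli_loglik <- function(y, eta) {
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

#' Fit one node's neighborhood
#'
#' Regresses symptom `node` on all other symptoms along the full penalty
#' path, scores every path model by [ebic_score()] (log-likelihood evaluated
#' without the penalty at the penalized coefficients), and returns the
#' EBIC-minimizing model; ties go to the larger penalty (sparser model).
#'
#' @param data a complete [binary_dataset()] (no missing cells).
#' @param node column index or symptom id.
#' @param config an [estimation_config()].
#' @return List of class `nodewise_result`: `node`, `node_id`, `intercept`,
#'   `neighbor_coefficients` (named length p-1 vector), `chosen_lambda`,
#'   `chosen_index`, `chosen_k`, `ebic_at_chosen`, and `path` (a data.frame
#'   with lambda, k and ebic for every path point).
#' @export
fit_node <- function(data, node, config = estimation_config()) {
  stopifnot(inherits(data, "binary_dataset"))
  v <- data$values
  if (anyNA(v)) {
    stop("dataset contains missing values; impute before estimation",
         call. = FALSE)
  }
  if (is.character(node)) node <- match(node, colnames(v))
  y <- as.numeric(v[, node])
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: column '", colnames(v)[node],
         "' is constant", call. = FALSE)
  }
  X <- v[, -node, drop = FALSE]
  storage.mode(X) <- "double"
  n <- nrow(v); p <- ncol(v)
  path <- lambda_path(y, X, config)
  fit <- .glmnet_path(y, X, path, config)
  beta <- as.matrix(fit$beta)            # (p-1) x n_lambda
  beta[abs(beta) < 1e-10] <- 0           # boundary solutions are exact zeros
  a0 <- as.numeric(fit$a0)
  scores <- vapply(seq_along(path), function(m) {
    nz <- which(beta[, m] != 0)
    k <- length(nz)
    if (config$refit && k > 0L) {
      re <- stats::glm.fit(cbind(1, X[, nz, drop = FALSE]), y,
                           family = stats::binomial())
      eta <- re$linear.predictors
    } else if (config$refit) {
      eta <- rep(stats::qlogis(mean(y)), n)
    } else {
      eta <- a0[m] + as.numeric(X %*% beta[, m])
    }
    ebic_score(.bernoulli_loglik(y, eta), k, n, p, config$gamma)
  }, numeric(1))
  best <- which.min(scores)              # first minimum = largest lambda
  coefs <- beta[, best]
  names(coefs) <- colnames(v)[-node]
  structure(list(node = node, node_id = colnames(v)[node],
                 intercept = a0[best], neighbor_coefficients = coefs,
                 chosen_lambda = path[best], chosen_index = best,
                 chosen_k = sum(coefs != 0), ebic_at_chosen = scores[best],
                 path = data.frame(lambda = path,
                                   k = colSums(beta != 0),
                                   ebic = scores)),
            class = "nodewise_result")
}

#' Combine nodewise fits into a symmetric network
#'
#' Builds the directed coefficient matrix B (row i = node i's regression),
#' then keeps edge (i, j) when both B_ij and B_ji are nonzero (`"AND"`) or
#' when either is (`"OR"`); a retained edge gets weight (B_ij + B_ji) / 2.
#'
#' @param results list of [fit_node()] results, one per node, in column
#'   order.
#' @param config an [estimation_config()] (supplies the rule).
#' @return A [symptom_network()].
#' @export
assemble_network <- function(results, config = estimation_config()) {
  p <- length(results)
  ids <- vapply(results, function(r) r$node_id, character(1))
  for (r in results) {
    if (length(r$neighbor_coefficients) != p - 1L) {
      stop("nodewise result for '", r$node_id, "' has ",
           length(r$neighbor_coefficients), " neighbors; expected ", p - 1L,
           call. = FALSE)
    }
  }
  B <- matrix(0, p, p, dimnames = list(ids, ids))
  for (i in seq_len(p)) {
    B[i, names(results[[i]]$neighbor_coefficients)] <-
      results[[i]]$neighbor_coefficients
  }
  keep <- if (config$rule == "AND") (B != 0) & (t(B) != 0) else
    (B != 0) | (t(B) != 0)
  W <- ifelse(keep, (B + t(B)) / 2, 0)
  diag(W) <- 0
  symptom_network(W, ids)
}

#' Estimate the symptom network
#'
#' The full nodewise procedure: one l1-penalized logistic regression per
#' symptom with EBIC penalty selection ([fit_node()]), symmetrized by
#' [assemble_network()]. Deterministic given data and config.
#'
#' @param data a complete [binary_dataset()]; every column must take both
#'   values.
#' @param config an [estimation_config()].
#' @return A [symptom_network()].
#' @export
estimate_network <- function(data, config = estimation_config()) {
  stopifnot(inherits(data, "binary_dataset"))
  v <- data$values
  if (anyNA(v)) {
    stop("dataset contains missing values; impute before estimation",
         call. = FALSE)
  }
  const <- colnames(v)[apply(v, 2, function(col) length(unique(col)) < 2L)]
  if (length(const) > 0L) {
    stop("degenerate outcome: constant column(s) prevent estimation: ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  results <- lapply(seq_len(ncol(v)), function(i) fit_node(data, i, config))
  assemble_network(results, config)
}
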