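#' Ising model parameters
#'
#' Thresholds (item main effects on the logit scale) and a symmetric
#' zero-diagonal coupling matrix for a pairwise binary Markov random field
#' in the \{0, 1\} parameterization.
#'
#' @param thresholds numeric vector of length p.
#' @param couplings symmetric p x p numeric matrix with zero diagonal.
#' @return Object of class `ising_parameters`.
#' @export
ising_parameters <- function(thresholds, couplings) {
  thresholds <- as.numeric(thresholds)
  couplings <- as.matrix(couplings)
  p <- length(thresholds)
  if (!all(dim(couplings) == c(p, p))) {
    stop("couplings must be ", p, " x ", p, call. = FALSE)
  }
  if (!all(is.finite(thresholds)) || !all(is.finite(couplings))) {
    stop("thresholds and couplings must be finite", call. = FALSE)
  }
  if (max(abs(couplings - t(couplings))) > 1e-12) {
    stop("couplings must be symmetric", call. = FALSE)
  }
  if (any(diag(couplings) != 0)) {
    stop("couplings must have a zero diagonal", call. = FALSE)
  }
  structure(list(thresholds = thresholds, couplings = couplings),
            class = "ising_parameters")
}

#' Block-structured Ising parameters for a symptom catalog
#'
#' Emulates the segregated structure of a diagnostic symptom network:
#' dense, mostly strong couplings inside each diagnosis block and sparse,
#' weaker couplings across blocks. Each within-block pair independently
#' receives a nonzero coupling with probability `within_density` (value
#' uniform on `within_weight_range`), each between-block pair with
#' probability `between_density` (uniform on `between_weight_range`);
#' thresholds are uniform on `threshold_range`.
#'
#' Defaults emulate a survey of fairly common, positively associated
#' symptoms: moderately dense positive within-block couplings, rare weak
#' between-block couplings, and negative thresholds so marginal symptom
#' prevalences stay well below one half.
#'
#' @param catalog a [symptom_catalog()].
#' @param within_density,between_density edge probabilities in \[0, 1\].
#' @param within_weight_range,between_weight_range numeric length-2
#'   intervals for coupling values (logit scale).
#' @param threshold_range numeric length-2 interval for thresholds.
#' @param seed integer seed; identical seed gives identical output.
#' @return An [ising_parameters()] whose coupling matrix carries the
#'   catalog's symptom ids as dimnames.
#' @export
make_block_parameters <- function(catalog,
                                  within_density = 0.6,
                                  between_density = 0.02,
                                  within_weight_range = c(0.2, 0.6),
                                  between_weight_range = c(0.1, 0.3),
                                  threshold_range = c(-3, -1.5),
                                  seed = 1L) {
  stopifnot(inherits(catalog, "symptom_catalog"))
  if (nrow(catalog$symptoms) == 0L) stop("catalog is empty", call. = FALSE)
  .check_prob(within_density, "within_density")
  .check_prob(between_density, "between_density")
  .check_range(within_weight_range, "within_weight_range")
  .check_range(between_weight_range, "between_weight_range")
  .check_range(threshold_range, "threshold_range")

  p <- nrow(catalog$symptoms)
  dx <- catalog$symptoms$diagnosis_code
  ids <- catalog$symptoms$symptom_id
  set.seed(seed)
  omega <- matrix(0, p, p, dimnames = list(ids, ids))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      if (dx[i] == dx[j]) {
        if (stats::runif(1) < within_density) {
          omega[i, j] <- stats::runif(1, within_weight_range[1],
                                      within_weight_range[2])
        }
      } else if (stats::runif(1) < between_density) {
        omega[i, j] <- stats::runif(1, between_weight_range[1],
                                    between_weight_range[2])
      }
      omega[j, i] <- omega[i, j]
    }
  }
  tau <- stats::runif(p, threshold_range[1], threshold_range[2])
  names(tau) <- ids
  ising_parameters(tau, omega)
}

#' Binary symptom dataset
#'
#' An n x p matrix of 0/1 symptom indicators with `NA` as the explicit
#' missing marker (used for skip-related missingness before imputation).
#'
#' @param values integer/numeric matrix over \{0, 1, NA\}.
#' @param column_ids symptom ids, in catalog order.
#' @param row_ids optional respondent ids (default `r1..rn`).
#' @return Object of class `binary_dataset` with element `values` (an
#'   integer matrix with dimnames).
#' @export
binary_dataset <- function(values, column_ids = colnames(values),
                           row_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(column_ids)) {
    stop("column_ids are required (symptom ids)", call. = FALSE)
  }
  if (length(column_ids) != ncol(values)) {
    stop("column_ids length does not match column count", call. = FALSE)
  }
  if (is.null(row_ids)) {
    row_ids <- if (nrow(values) == 0L) character(0) else
      paste0("r", seq_len(nrow(values)))
  }
  storage.mode(values) <- "integer"
  ok <- values %in% c(0L, 1L) | is.na(values)
  if (!all(ok)) stop("values must be 0, 1 or NA", call. = FALSE)
  dimnames(values) <- list(as.character(row_ids), as.character(column_ids))
  structure(list(values = values), class = "binary_dataset")
}

#' @export
print.binary_dataset <- function(x, ...) {
  v <- x$values
  cat("binary_dataset:", nrow(v), "respondents x", ncol(v), "symptoms; ",
      sprintf("%.1f%% missing cells\n", 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.binary_dataset <- function(x) dim(x$values)

#' Draw respondents from an Ising model by Gibbs sampling
#'
#' Single-site Gibbs updates in sequential site order; the full conditional
#' is `P(x_i = 1 | rest) = plogis(tau_i + sum_j omega_ij x_j)`. One row is
#' kept every `thin` sweeps after `burn_in` sweeps of burn-in.
#'
#' @param params an [ising_parameters()].
#' @param n number of rows to draw.
#' @param burn_in burn-in sweeps (default 1000).
#' @param thin keep every `thin`-th sweep (default 10).
#' @param seed integer seed; identical seed gives identical output.
#' @return A [binary_dataset()] with no missing values.
#' @export
gibbs_sample <- function(params, n, burn_in = 1000L, thin = 10L, seed = 1L) {
  stopifnot(inherits(params, "ising_parameters"))
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (thin <= 0) stop("thin must be positive", call. = FALSE)
  if (burn_in < 0) stop("burn_in must be nonnegative", call. = FALSE)
  set.seed(seed)
  values <- gibbs_sample_cpp(params$thresholds, params$couplings,
                             as.integer(n), as.integer(burn_in),
                             as.integer(thin))
  ids <- colnames(params$couplings)
  if (is.null(ids)) ids <- paste0("x", seq_along(params$thresholds))
  binary_dataset(values, column_ids = ids)
}

#' Impose screener skip-logic
#'
#' For every diagnosis that has screeners, rows failing the gating condition
#' get all that diagnosis's gated items set to missing (`NA`), mirroring a
#' structured interview that skips a section after a negative screen.
#' Screener columns and unscreened diagnoses are never touched.
#'
#' @param data a [binary_dataset()] whose columns match `catalog`.
#' @param catalog a [symptom_catalog()].
#' @param gate `"all"` (default): the section is skipped when ALL its
#'   screeners are 0; `"any"`: skipped when ANY screener is 0.
#' @return A [binary_dataset()] with skip-related `NA`s.
#' @export
apply_skip_logic <- function(data, catalog, gate = c("all", "any")) {
  gate <- match.arg(gate)
  stopifnot(inherits(data, "binary_dataset"),
            inherits(catalog, "symptom_catalog"))
  v <- data$values
  if (!identical(colnames(v), catalog$symptoms$symptom_id)) {
    stop("dataset columns do not match the catalog's symptoms", call. = FALSE)
  }
  for (dx in names(catalog$skip_rules)) {
    rule <- catalog$skip_rules[[dx]]
    if (length(rule$screeners) == 0L || length(rule$gated) == 0L) next
    scr <- v[, rule$screeners, drop = FALSE]
    if (anyNA(scr)) {
      stop("screener columns of ", dx, " contain missing values",
           call. = FALSE)
    }
    skipped <- if (gate == "all") rowSums(scr) == 0L else
      rowSums(scr == 0L) > 0L
    v[skipped, rule$gated] <- NA_integer_
  }
  binary_dataset(v)
}

#' Impute skipped items as absent
#'
#' Every missing cell becomes 0 (symptom absent); observed cells are
#' unchanged. This is the zero-imputation step that follows skip-logic in
#' the survey's coding.
#'
#' @param data a [binary_dataset()].
#' @return A [binary_dataset()] with no missing values.
#' @export
impute_skip_zeros <- function(data) {
  stopifnot(inherits(data, "binary_dataset"))
  v <- data$values
  v[is.na(v)] <- 0L
  binary_dataset(v)
}

#' Per-row missing fraction
#'
#' @param data a [binary_dataset()].
#' @return Numeric vector in \[0, 1\] of length n: the share of missing
#'   cells in each row.
#' @export
row_missing_fraction <- function(data) {
  stopifnot(inherits(data, "binary_dataset"))
  rowMeans(is.na(data$values))
}

#' Filter rows by missingness
#'
#' Keeps exactly the rows whose missing fraction is strictly below
#' `max_fraction` (so `max_fraction = 0.2` keeps rows with "less than 20%"
#' missing), preserving row order. Fully observed rows are always retained,
#' so a threshold of 0 keeps exactly the complete cases.
#'
#' @param data a [binary_dataset()].
#' @param max_fraction threshold in \[0, 1\].
#' @return A [binary_dataset()].
#' @export
filter_rows_by_missingness <- function(data, max_fraction) {
  stopifnot(inherits(data, "binary_dataset"))
  if (max_fraction < 0 || max_fraction > 1) {
    stop("max_fraction must be in [0, 1]", call. = FALSE)
  }
  frac <- row_missing_fraction(data)
  keep <- frac == 0 | frac < max_fraction
  binary_dataset(data$values[keep, , drop = FALSE],
                 column_ids = colnames(data$values))
}

#' Write / read a binary dataset as CSV
#'
#' Header = symptom ids, one row per respondent, missing cells encoded as an
#' empty field by default. `write_dataset` also writes a `<path>.json`
#' sidecar recording the seed/parameters passed in `provenance`.
#'
#' @param data a [binary_dataset()].
#' @param path CSV file path.
#' @param missing_token string written for missing cells (default `""`).
#' @param provenance optional list stored in the JSON sidecar.
#' @return `path`, invisibly (`write_dataset`); a [binary_dataset()]
#'   (`read_dataset`).
#' @export
write_dataset <- function(data, path, missing_token = "",
                          provenance = NULL) {
  stopifnot(inherits(data, "binary_dataset"))
  utils::write.table(data$values, path, sep = ",", na = missing_token,
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  if (!is.null(provenance)) {
    jsonlite::write_json(provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, missing_token = "") {
  values <- as.matrix(utils::read.csv(path, check.names = FALSE,
                                      na.strings = missing_token,
                                      colClasses = "integer"))
  binary_dataset(values, column_ids = colnames(values))
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a probability in [0, 1]", call. = FALSE)
  }
}

.check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2]) {
    stop(name, " must be a finite interval c(lo, hi)", call. = FALSE)
  }
}
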