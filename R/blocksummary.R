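#' Round half away from zero
#'
#' Fixed-point rounding used for the printed percentage cells (e.g. 6.875
#' displays as 6.9), avoiding R's round-half-to-even convention.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Connection percentage of a block cell
#'
#' `100 * realized / potential`, the quantity printed in the connectivity
#' table; 0 when `potential` is 0.
#'
#' @param realized,potential nonnegative counts.
#' @param digits decimal places for display rounding; `NULL` returns full
#'   precision.
#' @return Percentage(s) on the 0-100 scale.
#' @export
connection_percent <- function(realized, potential, digits = 1) {
  pct <- ifelse(potential > 0, 100 * realized / potential, 0)
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Within/between-diagnosis connectivity summary
#'
#' Partitions the network's edges (any nonzero weight, either sign) by the
#' diagnosis membership of their endpoints and reports realized counts,
#' potential counts ([potential_within()], [potential_between()]) and
#' percentages — the structure of the published "connections within and
#' between diagnoses" table. The `all_other` rows follow that table's
#' denominator convention n_dx * p (see [potential_all_other()]).
#'
#' @param network a [symptom_network()] whose node ids match `catalog`.
#' @param catalog a [symptom_catalog()].
#' @return Object of class `block_summary`: data.frames `within`
#'   (diagnosis, realized, potential, percent), `between` (dx1, dx2, ...,
#'   one row per unordered pair), `all_other`, and named integer vector
#'   `diagnosis_partners` (other diagnoses with >= 1 connecting edge).
#'   Percentages are stored at full precision.
#' @export
summarize_blocks <- function(network, catalog) {
  stopifnot(inherits(network, "symptom_network"),
            inherits(catalog, "symptom_catalog"))
  if (!identical(network$node_ids, catalog$symptoms$symptom_id)) {
    stop("network node ids do not match the catalog's symptoms",
         call. = FALSE)
  }
  W <- network$weights
  dx <- catalog$symptoms$diagnosis_code
  dxs <- diagnoses(catalog)
  nd <- length(dxs)

  realized <- matrix(0L, nd, nd, dimnames = list(dxs, dxs))
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    a <- dx[idx[r, 1]]; b <- dx[idx[r, 2]]
    realized[a, b] <- realized[a, b] + 1L
    if (a != b) realized[b, a] <- realized[b, a] + 1L
  }

  within <- data.frame(
    diagnosis = dxs,
    realized = diag(realized)[dxs],
    potential = vapply(dxs, potential_within, integer(1), catalog = catalog),
    stringsAsFactors = FALSE, row.names = NULL)
  within$percent <- connection_percent(within$realized, within$potential,
                                       digits = NULL)

  pairs <- which(upper.tri(matrix(0, nd, nd)), arr.ind = TRUE)
  between <- data.frame(
    dx1 = dxs[pairs[, 1]], dx2 = dxs[pairs[, 2]],
    realized = realized[pairs],
    potential = mapply(function(a, b) potential_between(catalog, a, b),
                       dxs[pairs[, 1]], dxs[pairs[, 2]]),
    stringsAsFactors = FALSE, row.names = NULL)
  between$percent <- connection_percent(between$realized, between$potential,
                                        digits = NULL)

  off <- realized; diag(off) <- 0L
  all_other <- data.frame(
    diagnosis = dxs,
    realized = as.integer(rowSums(off))[match(dxs, rownames(realized))],
    potential = vapply(dxs, potential_all_other, integer(1),
                       catalog = catalog),
    stringsAsFactors = FALSE, row.names = NULL)
  all_other$percent <- connection_percent(all_other$realized,
                                          all_other$potential, digits = NULL)

  partners <- vapply(dxs, function(d) sum(off[d, ] >= 1L), integer(1))

  structure(list(within = within, between = between, all_other = all_other,
                 diagnosis_partners = partners),
            class = "block_summary")
}

#' Build a block summary from printed counts
#'
#' Constructs a `block_summary` directly from a table of realized/potential
#' counts (one row per within cell with `dx1 == dx2`, one per unordered
#' between pair), e.g. a transcription of a published connectivity table.
#' Percentages and the per-diagnosis aggregates are recomputed, not copied.
#'
#' @param counts data.frame with columns `dx1`, `dx2`, `realized`,
#'   `potential`.
#' @param p total symptom count (used for the `all_other` denominator
#'   n_dx * p); diagnosis sizes are recovered from the within potentials.
#' @return A `block_summary`.
#' @export
block_summary_from_counts <- function(counts, p = 120L) {
  stopifnot(all(c("dx1", "dx2", "realized", "potential") %in% names(counts)))
  w <- counts[counts$dx1 == counts$dx2, ]
  b <- counts[counts$dx1 != counts$dx2, ]
  dxs <- w$dx1
  # n(n-1)/2 = potential => n = (1 + sqrt(1 + 8 potential)) / 2
  sizes <- as.integer(round((1 + sqrt(1 + 8 * w$potential)) / 2))
  names(sizes) <- dxs

  within <- data.frame(diagnosis = dxs, realized = as.integer(w$realized),
                       potential = as.integer(w$potential),
                       stringsAsFactors = FALSE, row.names = NULL)
  within$percent <- connection_percent(within$realized, within$potential,
                                       digits = NULL)
  between <- data.frame(dx1 = b$dx1, dx2 = b$dx2,
                        realized = as.integer(b$realized),
                        potential = as.integer(b$potential),
                        stringsAsFactors = FALSE, row.names = NULL)
  between$percent <- connection_percent(between$realized, between$potential,
                                        digits = NULL)
  all_other <- data.frame(
    diagnosis = dxs,
    realized = vapply(dxs, function(d) {
      sum(between$realized[between$dx1 == d | between$dx2 == d])
    }, integer(1)),
    potential = as.integer(sizes * p),
    stringsAsFactors = FALSE, row.names = NULL)
  all_other$percent <- connection_percent(all_other$realized,
                                          all_other$potential, digits = NULL)
  partners <- vapply(dxs, function(d) {
    sum(between$realized[between$dx1 == d | between$dx2 == d] >= 1L)
  }, integer(1))
  structure(list(within = within, between = between, all_other = all_other,
                 diagnosis_partners = partners),
            class = "block_summary")
}

#' @export
print.block_summary <- function(x, ...) {
  cat("block_summary:", nrow(x$within), "diagnoses;",
      sum(x$within$realized), "within +", sum(x$between$realized),
      "between edges\n")
  invisible(x)
}

#' Format a block summary as the published lower-triangular table
#'
#' One "percent (realized/potential)" cell per diagnosis pair, diagnoses in
#' table order down the rows and across the columns, within-diagnosis
#' diagonal cells wrapped in `*asterisks*` (the plain-text bold convention);
#' the final row aggregates each diagnosis against all other diagnoses.
#' Percentages are rounded half-up to one decimal.
#'
#' @param summary a `block_summary`.
#' @param path optional file path; when given the table is also written as
#'   TSV.
#' @return A character matrix (invisibly when `path` is given).
#' @export
format_table1 <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "block_summary"))
  dxs <- summary$within$diagnosis
  nd <- length(dxs)
  if (nd == 0L) {
    out <- matrix(character(0), 0, 0)
    if (!is.null(path)) utils::write.table(out, path, sep = "\t")
    return(out)
  }
  cell <- function(realized, potential, bold = FALSE) {
    pct <- connection_percent(realized, potential)
    s <- sprintf("%.1f%% (%d/%d)", pct, realized, potential)
    if (bold) paste0("*", s, "*") else s
  }
  out <- matrix("", nd + 1L, nd, dimnames = list(c(dxs, "All other"), dxs))
  for (i in seq_len(nd)) {
    out[i, i] <- cell(summary$within$realized[i],
                      summary$within$potential[i], bold = TRUE)
    if (i > 1L) for (j in seq_len(i - 1L)) {
      row <- summary$between[
        (summary$between$dx1 == dxs[i] & summary$between$dx2 == dxs[j]) |
        (summary$between$dx1 == dxs[j] & summary$between$dx2 == dxs[i]), ]
      out[i, j] <- cell(row$realized[1], row$potential[1])
    }
  }
  for (j in seq_len(nd)) {
    out[nd + 1L, j] <- cell(summary$all_other$realized[j],
                            summary$all_other$potential[j])
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       col.names = NA)
    return(invisible(out))
  }
  out
}

#' Parse a formatted table back to counts
#'
#' Inverse of [format_table1()]'s TSV export: recovers every
#' realized/potential pair exactly.
#'
#' @param path TSV file written by [format_table1()].
#' @return data.frame with `dx1`, `dx2`, `realized`, `potential` (within
#'   cells have `dx1 == dx2`; the "All other" row is skipped).
#' @export
parse_table1 <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE,
                           stringsAsFactors = FALSE)
  dxs <- colnames(tab)
  rows <- list()
  for (i in seq_along(dxs)) {
    for (j in seq_len(i)) {
      s <- tab[i, j]
      m <- regmatches(s, regexec("\\((\\d+)/(\\d+)\\)", s))[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        dx1 = dxs[i], dx2 = dxs[j],
        realized = as.integer(m[2]), potential = as.integer(m[3]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
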