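#' Published block-level connection counts
#'
#' The realized/potential connection counts of the published within/between
#' diagnosis table (12 within cells and 66 between cells), shipped as a
#' plain-text transcription. These counts are printed results used as
#' inputs: percentage and aggregate computations on them are recomputed by
#' this package, never copied.
#'
#' @return data.frame with columns `dx1`, `dx2`, `realized`, `potential`
#'   (within rows have `dx1 == dx2`).
#' @export
published_table1_counts <- function() {
  path <- system.file("extdata", "table1_counts.tsv", package = "symptomnet",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Synthetic network matching published block counts
#'
#' Builds a stand-in weighted network whose within- and between-diagnosis
#' edge COUNTS equal a table of published block counts exactly, placing the
#' edges uniformly at random inside each block and drawing weights from a
#' simple magnitude/sign model. This is a synthetic surrogate for the
#' (unavailable) full published weight matrix: block-level quantities
#' (counts, percentages, diagnosis partners, node count) are faithful by
#' construction, while node-level placement — and hence clustering and path
#' lengths — is random and NOT the published network's.
#'
#' @param catalog a [symptom_catalog()] whose diagnosis sizes match the
#'   count table's potentials.
#' @param counts count table as from [published_table1_counts()].
#' @param seed integer seed.
#' @param weight_range magnitude interval for edge weights.
#' @param prob_negative probability an edge weight is negative.
#' @return A [symptom_network()].
#' @export
synthetic_table1_network <- function(catalog,
                                     counts = published_table1_counts(),
                                     seed = 1L,
                                     weight_range = c(0.2, 1.2),
                                     prob_negative = 0.05) {
  stopifnot(inherits(catalog, "symptom_catalog"))
  ids <- catalog$symptoms$symptom_id
  dx <- catalog$symptoms$diagnosis_code
  p <- length(ids)
  set.seed(seed)
  W <- matrix(0, p, p, dimnames = list(ids, ids))
  place <- function(idx_a, idx_b, realized, potential, within) {
    pairs <- if (within) t(utils::combn(idx_a, 2)) else
      as.matrix(expand.grid(idx_a, idx_b))
    if (nrow(pairs) != potential) {
      stop("catalog block sizes do not match the count table (",
           nrow(pairs), " pairs vs potential ", potential, ")",
           call. = FALSE)
    }
    if (realized == 0L) return(invisible())
    sel <- pairs[sample.int(nrow(pairs), realized), , drop = FALSE]
    w <- stats::runif(realized, weight_range[1], weight_range[2]) *
      ifelse(stats::runif(realized) < prob_negative, -1, 1)
    for (r in seq_len(realized)) {
      W[sel[r, 1], sel[r, 2]] <<- w[r]
      W[sel[r, 2], sel[r, 1]] <<- w[r]
    }
  }
  for (r in seq_len(nrow(counts))) {
    a <- which(dx == counts$dx1[r]); b <- which(dx == counts$dx2[r])
    if (length(a) == 0L || length(b) == 0L) {
      stop("count table names a diagnosis absent from the catalog: ",
           counts$dx1[r], "/", counts$dx2[r], call. = FALSE)
    }
    place(a, b, counts$realized[r], counts$potential[r],
          within = counts$dx1[r] == counts$dx2[r])
  }
  symptom_network(W, ids)
}
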