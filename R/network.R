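#' Weighted symptom network
#'
#' A symmetric weighted adjacency matrix over symptoms with zero diagonal;
#' the object behind the published connection-strength table.
#'
#' @param weights symmetric numeric p x p matrix, zero diagonal, finite.
#' @param node_ids symptom ids (default taken from dimnames).
#' @return Object of class `symptom_network` with elements `weights` and
#'   `node_ids`.
#' @export
symptom_network <- function(weights, node_ids = colnames(weights)) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (ncol(weights) != p) stop("weights must be square", call. = FALSE)
  if (is.null(node_ids)) node_ids <- paste0("v", seq_len(p))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != p) {
    stop("node_ids length does not match matrix size", call. = FALSE)
  }
  if (!all(is.finite(weights))) {
    stop("weights must be finite", call. = FALSE)
  }
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop("weights must be symmetric", call. = FALSE)
  }
  if (any(diag(weights) != 0)) {
    stop("weights must have a zero diagonal", call. = FALSE)
  }
  dimnames(weights) <- list(node_ids, node_ids)
  structure(list(weights = weights, node_ids = node_ids),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  ut <- x$weights[upper.tri(x$weights)]
  cat("symptom_network:", length(x$node_ids), "nodes,", sum(ut != 0),
      "edges (", sum(ut > 0), "positive /", sum(ut < 0), "negative )\n")
  invisible(x)
}

#' Number of (unordered) edges of a network
#' @param network a [symptom_network()].
#' @return Integer count of nonzero upper-triangle weights.
#' @export
edge_count <- function(network) {
  stopifnot(inherits(network, "symptom_network"))
  sum(network$weights[upper.tri(network$weights)] != 0)
}
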