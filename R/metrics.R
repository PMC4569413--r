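#' Unweighted graph from a weighted network
#'
#' A connection is any strictly nonzero weight, positive or negative; the
#' descriptive statistics below are computed on this binarized graph.
#'
#' @param network a [symptom_network()].
#' @return Object of class `binary_graph` with a logical symmetric
#'   `adjacency` matrix (zero diagonal) and `node_ids`.
#' @export
binarize <- function(network) {
  stopifnot(inherits(network, "symptom_network"))
  adj <- network$weights != 0
  diag(adj) <- FALSE
  structure(list(adjacency = adj, node_ids = network$node_ids),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("binary_graph:", length(x$node_ids), "nodes,",
      sum(x$adjacency[upper.tri(x$adjacency)]), "edges\n")
  invisible(x)
}

# igraph view of a binary_graph.
.as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency * 1,
                                      mode = "undirected", diag = FALSE)
}

#' Is the graph one connected component?
#'
#' @param graph a [binarize()]d graph.
#' @return `TRUE` iff every node is reachable from every other.
#' @export
is_connected <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  igraph::is_connected(.as_igraph(graph))
}

#' Clustering coefficient
#'
#' Three conventions are available because a single printed "clustering
#' coefficient" does not identify its estimator:
#' `average_local_zero` averages the local coefficient
#' `C_i = 2 t_i / (d_i (d_i - 1))` over all nodes, scoring nodes with degree
#' below 2 as 0; `average_local_exclude` averages only over nodes with
#' degree >= 2; `transitivity` is the global ratio 3 x triangles / connected
#' triples.
#'
#' @param graph a [binarize()]d graph with at least one node.
#' @param convention one of `"average_local_zero"` (default),
#'   `"average_local_exclude"`, `"transitivity"`.
#' @return A number in \[0, 1\].
#' @export
clustering_coefficient <- function(graph,
                                   convention = c("average_local_zero",
                                                  "average_local_exclude",
                                                  "transitivity")) {
  stopifnot(inherits(graph, "binary_graph"))
  convention <- match.arg(convention)
  if (length(graph$node_ids) == 0L) stop("graph has no nodes", call. = FALSE)
  g <- .as_igraph(graph)
  if (convention == "transitivity") {
    val <- igraph::transitivity(g, type = "global")
    return(if (is.nan(val)) 0 else val)
  }
  local <- igraph::transitivity(g, type = "local", isolates = "NaN")
  if (convention == "average_local_zero") {
    local[is.nan(local)] <- 0
    return(mean(local))
  }
  if (all(is.nan(local))) return(0)
  mean(local[!is.nan(local)])
}

#' Average shortest path length
#'
#' Mean hop count of the shortest path over all unordered node pairs of a
#' connected graph.
#'
#' @param graph a connected [binarize()]d graph.
#' @param on_disconnected `"error"` (default) or `"largest_component"`,
#'   which computes the mean inside the largest component and warns.
#' @return A number >= 1 (for any graph with at least one edge).
#' @export
average_shortest_path_length <- function(graph,
                                         on_disconnected = c("error",
                                                             "largest_component")) {
  stopifnot(inherits(graph, "binary_graph"))
  on_disconnected <- match.arg(on_disconnected)
  g <- .as_igraph(graph)
  if (!igraph::is_connected(g)) {
    comp <- igraph::components(g)
    if (on_disconnected == "error") {
      sizes <- paste(comp$csize, collapse = ", ")
      stop("graph is disconnected (", comp$no, " components of sizes ",
           sizes, ")", call. = FALSE)
    }
    warning("graph is disconnected; using the largest component (",
            max(comp$csize), " of ", length(graph$node_ids), " nodes)",
            call. = FALSE)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  igraph::mean_distance(g, directed = FALSE)
}

#' Node degrees with a min/mean/max summary
#'
#' @param graph a [binarize()]d graph.
#' @return List with `degrees` (named integer vector, row sums of the
#'   adjacency) and `summary` (min, mean, max).
#' @export
degree_summary <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  d <- rowSums(graph$adjacency)
  names(d) <- graph$node_ids
  list(degrees = d,
       summary = c(min = min(d), mean = mean(d), max = max(d)))
}

#' All descriptives of a network in one report
#'
#' @param network a [symptom_network()].
#' @return List: `nodes`, `edges`, `connected`, `clustering` (all three
#'   conventions), `aspl` (NA when disconnected), `degree` summary.
#' @export
network_descriptives <- function(network) {
  g <- binarize(network)
  connected <- is_connected(g)
  list(
    nodes = length(g$node_ids),
    edges = sum(g$adjacency[upper.tri(g$adjacency)]),
    connected = connected,
    clustering = c(
      average_local_zero = clustering_coefficient(g, "average_local_zero"),
      average_local_exclude = clustering_coefficient(g, "average_local_exclude"),
      transitivity = clustering_coefficient(g, "transitivity")),
    aspl = if (connected) average_shortest_path_length(g) else NA_real_,
    degree = degree_summary(g)$summary
  )
}
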