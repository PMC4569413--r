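#' Read a labeled weight matrix
#'
#' Ingests a square, labeled connection-strength matrix (the shape of the
#' published supplementary table). Asymmetries below `1e-8` are averaged
#' away; larger ones are an error reporting the worst cell. A nonzero
#' diagonal is zeroed with a warning. Unparseable cells or a non-square
#' shape are errors, never coerced.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"` (default inferred from the extension).
#' @return A [symptom_network()].
#' @export
read_weight_matrix <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- ifelse(tolower(tools::file_ext(path)) == "tsv", "tsv", "csv")
  }
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  W <- as.matrix(raw)
  if (nrow(W) != ncol(W)) {
    stop("weight matrix is not square: ", nrow(W), " x ", ncol(W),
         call. = FALSE)
  }
  if (!is.numeric(W) || anyNA(W)) {
    stop("weight matrix contains unparseable or missing cells",
         call. = FALSE)
  }
  asym <- abs(W - t(W))
  if (max(asym) > 1e-8) {
    worst <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop("weight matrix is asymmetric; worst cell (",
         rownames(W)[worst[1]], ", ", colnames(W)[worst[2]], ") differs by ",
         signif(max(asym), 3), call. = FALSE)
  }
  W <- (W + t(W)) / 2
  if (any(diag(W) != 0)) {
    warning("nonzero diagonal entries set to 0", call. = FALSE)
    diag(W) <- 0
  }
  symptom_network(W, rownames(W))
}

#' Write a network's weight matrix
#'
#' @param network a [symptom_network()].
#' @param path output path.
#' @param format `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_weight_matrix <- function(network, path, format = "csv") {
  stopifnot(inherits(network, "symptom_network"))
  sep <- if (format == "tsv") "\t" else ","
  utils::write.table(network$weights, path, sep = sep, quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Tidy edge list of a network
#'
#' @param network a [symptom_network()].
#' @return data.frame `node_a`, `node_b`, `weight`, one row per nonzero
#'   edge, with `node_a` preceding `node_b` in node order.
#' @export
edge_list <- function(network) {
  stopifnot(inherits(network, "symptom_network"))
  W <- network$weights
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  data.frame(node_a = network$node_ids[idx[, 1]],
             node_b = network$node_ids[idx[, 2]],
             weight = W[idx], stringsAsFactors = FALSE)
}

# igraph object with the attributes the exports carry.
.network_igraph <- function(network, catalog = NULL) {
  g <- igraph::graph_from_adjacency_matrix(network$weights,
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$sign <- ifelse(igraph::E(g)$weight >= 0, "positive",
                              "negative")
  if (!is.null(catalog)) {
    m <- match(network$node_ids, catalog$symptoms$symptom_id)
    if (anyNA(m)) {
      stop("network node ids do not match the catalog", call. = FALSE)
    }
    igraph::V(g)$diagnosis <- catalog$symptoms$diagnosis_code[m]
    igraph::V(g)$within_diagnosis_number <-
      catalog$symptoms$within_diagnosis_number[m]
  }
  g
}

#' Export a network to standard formats
#'
#' Writes any subset of: the full weight matrix (`matrix_csv`), a tidy edge
#' list of the nonzero edges (`edge_list_tsv`), and GraphML carrying weight
#' and sign edge attributes plus diagnosis and node-number vertex attributes
#' (`graphml`, requires `catalog`).
#'
#' @param network a [symptom_network()].
#' @param stem output path stem; files get `.csv`, `_edges.tsv`, `.graphml`.
#' @param catalog a [symptom_catalog()] (needed for GraphML attributes).
#' @param formats character subset of
#'   `c("matrix_csv", "edge_list_tsv", "graphml")`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_network <- function(network, stem, catalog = NULL,
                          formats = c("matrix_csv", "edge_list_tsv",
                                      "graphml")) {
  stopifnot(inherits(network, "symptom_network"))
  formats <- match.arg(formats, several.ok = TRUE)
  out <- character(0)
  if ("matrix_csv" %in% formats) {
    f <- paste0(stem, ".csv")
    write_weight_matrix(network, f)
    out["matrix_csv"] <- f
  }
  if ("edge_list_tsv" %in% formats) {
    f <- paste0(stem, "_edges.tsv")
    utils::write.table(edge_list(network), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out["edge_list_tsv"] <- f
  }
  if ("graphml" %in% formats) {
    f <- paste0(stem, ".graphml")
    igraph::write_graph(.network_igraph(network, catalog), f,
                        format = "graphml")
    out["graphml"] <- f
  }
  invisible(out)
}

#' Read a network from GraphML
#'
#' @param path GraphML file written by [write_network()].
#' @return A [symptom_network()].
#' @export
read_graphml_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  has_w <- "weight" %in% igraph::edge_attr_names(g)
  W <- if (has_w) {
    as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
  } else {
    matrix(0, igraph::vcount(g), igraph::vcount(g))
  }
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- igraph::V(g)$id
  symptom_network(W, ids)
}

#' Force-directed layout
#'
#' Fruchterman-Reingold layout in which the absolute edge weight acts as the
#' attraction strength, so strongly and/or densely connected symptoms end up
#' close together. Seeded and deterministic; a single node is placed at the
#' origin.
#'
#' @param network a [symptom_network()].
#' @param seed integer seed.
#' @param iterations number of layout iterations (default 500).
#' @return Object of class `layout_coordinates`: `positions` (p x 2 matrix,
#'   rownames = node ids), `seed`, `iterations`.
#' @export
fruchterman_reingold <- function(network, seed = 1L, iterations = 500L) {
  stopifnot(inherits(network, "symptom_network"))
  if (iterations <= 0) stop("iterations must be positive", call. = FALSE)
  p <- length(network$node_ids)
  if (p == 1L) {
    pos <- matrix(0, 1, 2, dimnames = list(network$node_ids, c("x", "y")))
  } else {
    g <- .network_igraph(network)
    set.seed(seed)
    w <- if (igraph::ecount(g) > 0) abs(igraph::E(g)$weight) else NULL
    pos <- igraph::layout_with_fr(g, weights = w,
                                  niter = as.integer(iterations))
    dimnames(pos) <- list(network$node_ids, c("x", "y"))
  }
  if (!all(is.finite(pos))) stop("layout produced non-finite coordinates",
                                 call. = FALSE)
  structure(list(positions = pos, seed = as.integer(seed),
                 iterations = as.integer(iterations)),
            class = "layout_coordinates")
}

# Diagnosis -> fill color, recycled from a fixed palette.
.diagnosis_palette <- function(dxs) {
  pal <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
           "#FFFF33", "#A65628", "#F781BF", "#999999", "#66C2A5",
           "#FC8D62", "#8DA0CB")
  stats::setNames(rep_len(pal, length(dxs)), dxs)
}

#' Render a network figure
#'
#' Positive edges are drawn green and negative edges red, edge width is
#' proportional to the absolute weight, node fill color encodes the
#' diagnosis, and the node label is the symptom's number within its
#' diagnosis. Output format follows the file extension (`.svg`, `.pdf` or
#' `.png`).
#'
#' @param network a [symptom_network()].
#' @param catalog a [symptom_catalog()] matching the network.
#' @param layout a [fruchterman_reingold()] layout covering all nodes.
#' @param path output image path.
#' @param width_scale stroke width per unit of absolute weight (default 2).
#' @return `path`, invisibly.
#' @export
render_network <- function(network, catalog, layout, path,
                           width_scale = 2) {
  stopifnot(inherits(network, "symptom_network"),
            inherits(catalog, "symptom_catalog"),
            inherits(layout, "layout_coordinates"))
  if (!all(network$node_ids %in% rownames(layout$positions))) {
    stop("layout does not cover all network nodes", call. = FALSE)
  }
  pos <- layout$positions[network$node_ids, , drop = FALSE]
  m <- match(network$node_ids, catalog$symptoms$symptom_id)
  if (anyNA(m)) stop("network node ids do not match the catalog",
                     call. = FALSE)
  dx <- catalog$symptoms$diagnosis_code[m]
  labels <- catalog$symptoms$within_diagnosis_number[m]
  fill <- .diagnosis_palette(unique(dx))[dx]

  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = 9, height = 9),
         pdf = grDevices::pdf(path, width = 9, height = 9),
         png = grDevices::png(path, width = 1800, height = 1800,
                              res = 200),
         stop("unsupported image format: .", ext, call. = FALSE))
  on.exit(grDevices::dev.off())
  pad <- 0.08 * max(diff(range(pos[, 1])), diff(range(pos[, 2])), 1)
  graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  graphics::plot(NA, xlim = range(pos[, 1]) + c(-pad, pad),
                 ylim = range(pos[, 2]) + c(-pad, pad),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  el <- edge_list(network)
  if (nrow(el) > 0L) {
    graphics::segments(pos[el$node_a, 1], pos[el$node_a, 2],
                       pos[el$node_b, 1], pos[el$node_b, 2],
                       col = ifelse(el$weight >= 0, "#008B00", "#CD0000"),
                       lwd = pmin(width_scale * abs(el$weight), 12))
  }
  graphics::points(pos, pch = 21, bg = fill, col = "black",
                   cex = 2.2)
  graphics::text(pos, labels = labels, cex = 0.55)
  invisible(path)
}
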