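#' Read an undirected simple graph from a plain-text edge list
#'
#' Parses a whitespace-separated edge list: one edge per line, first two
#' tokens are the endpoint labels, any further tokens (e.g. weights) are
#' ignored, and lines whose first non-blank character is `#` are comments.
#' The result is always an undirected simple graph: self-loops are dropped,
#' duplicate edges (in either orientation) are merged, and edge direction is
#' discarded. Vertex names keep the original labels, with internal indices
#' assigned in order of first appearance.
#'
#' @param path Path to the edge-list file.
#' @param directed_as_undirected Kept for interface clarity; directions are
#'   always discarded. Defaults to `TRUE`.
#' @return An undirected simple [igraph][igraph::igraph-package] graph.
#' @seealso [write_edge_list()], [giant_component()]
#' @export
read_edge_list <- function(path, directed_as_undirected = TRUE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed edge list: line ", lineno[bad[1L]],
         " has fewer than two tokens")
  }
  if (!length(toks)) stop("empty edge list: ", path, " contains no edges")
  ends <- t(vapply(toks, function(x) x[1:2], character(2)))
  labels <- unique(as.vector(t(ends)))  # first-appearance order
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  g <- igraph::permute(g, match(igraph::V(g)$name, labels))
  simplify_graph(g)
}

#' Write a graph as a plain-text edge list
#'
#' One line per edge, endpoints as original vertex labels (internal indices
#' if the graph is unnamed), each unordered pair exactly once, in
#' deterministic sorted order. A round trip through [read_edge_list()]
#' recovers the same edge set.
#'
#' @param graph An undirected igraph graph.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  i <- pmin(el[, 1], el[, 2]); j <- pmax(el[, 1], el[, 2])
  ord <- order(i, j)
  lab <- vertex_labels(graph)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# undirected simple graph: %d nodes, %d edges",
                     igraph::vcount(graph), igraph::ecount(graph)), con)
  if (length(ord)) writeLines(paste(lab[i[ord]], lab[j[ord]]), con)
  invisible(path)
}

vertex_labels <- function(graph) {
  if (is.null(igraph::V(graph)$name)) as.character(seq_len(igraph::vcount(graph)))
  else as.character(igraph::V(graph)$name)
}

#' Simplify a graph to an undirected simple graph
#'
#' Drops self-loops, merges duplicate/multi-edges and discards directions.
#' Idempotent.
#'
#' @param graph An igraph graph.
#' @return An undirected simple igraph graph.
#' @export
simplify_graph <- function(graph) {
  g <- igraph::as_undirected(graph, mode = "collapse")
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Extract the giant component
#'
#' Returns the induced subgraph on the largest connected component.
#' Ties on size are broken in favour of the component containing the
#' smallest vertex index. Vertex indices are re-compacted; names are kept.
#'
#' @param graph An undirected igraph graph with at least one vertex.
#' @return The giant component as an igraph graph.
#' @export
giant_component <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("graph has no vertices")
  comp <- igraph::components(graph)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    # smallest minimum member index wins
    first_member <- vapply(big, function(b) min(which(comp$membership == b)), 1L)
    big <- big[which.min(first_member)]
  }
  igraph::induced_subgraph(graph, which(comp$membership == big))
}

#' Structural features of a connected network
#'
#' Computes the standard descriptive features of a connected undirected
#' simple graph: node count `N`, edge count `M`, mean degree `K = 2M/N`,
#' maximum degree `Delta`, hop-count diameter `D`, clustering coefficient
#' `C` (mean local clustering in the Watts-Strogatz sense; nodes of degree
#' < 2 contribute 0), global transitivity as a secondary field, and degree
#' assortativity `rho` (Pearson correlation of endpoint degrees over edges
#' counted in both orientations). On degree-regular graphs `rho` is 0/0 and
#' is reported as `NA` rather than an error.
#'
#' @param graph A connected undirected simple igraph graph with >= 2 nodes.
#' @return A list of class `network_features` with fields `N`, `M`, `K`,
#'   `Delta`, `D`, `C`, `transitivity`, `rho`.
#' @export
network_features <- function(graph) {
  if (igraph::vcount(graph) < 2L) stop("need at least 2 nodes")
  if (!igraph::is_connected(graph)) {
    stop("graph is disconnected; extract giant_component() first")
  }
  n <- igraph::vcount(graph); m <- igraph::ecount(graph)
  deg <- igraph::degree(graph)
  local_c <- igraph::transitivity(graph, type = "localundirected",
                                  isolates = "zero")
  rho <- suppressWarnings(igraph::assortativity_degree(graph, directed = FALSE))
  if (is.nan(rho)) rho <- NA_real_
  out <- list(
    N = n, M = m, K = 2 * m / n, Delta = max(deg),
    D = igraph::diameter(graph, directed = FALSE, unconnected = FALSE),
    C = mean(local_c),
    transitivity = igraph::transitivity(graph, type = "global"),
    rho = rho
  )
  class(out) <- "network_features"
  out
}

#' @export
print.network_features <- function(x, ...) {
  cat("Network features\n")
  cat(sprintf("  N = %d  M = %d  K = %.3f  Delta = %d  D = %d\n",
              x$N, x$M, x$K, x$Delta, x$D))
  cat(sprintf("  C (mean local) = %.4f  transitivity = %.4f  rho = %s\n",
              x$C, x$transitivity,
              if (is.na(x$rho)) "undefined" else sprintf("%.4f", x$rho)))
  invisible(x)
}
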