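# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# count walks of length `len` from x to y by exhaustive recursion over the
# adjacency list
walks_brute <- function(graph, x, y, len) {
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)),
                as.integer)
  rec <- function(v, remaining) {
    if (remaining == 0L) return(as.integer(v == y))
    sum(vapply(adj[[v]], rec, 1L, remaining = remaining - 1L))
  }
  rec(x, len)
}

# Pearson correlation of endpoint degrees over edges, both orientations
assortativity_brute <- function(graph) {
  deg <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  a <- c(deg[el[, 1]], deg[el[, 2]])
  b <- c(deg[el[, 2]], deg[el[, 1]])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# mean local clustering, triangles/(k choose 2), degree < 2 contributes 0
clustering_brute <- function(graph) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  loc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / 2 / choose(k, 2)
  }, 1)
  mean(loc)
}

# diameter by Floyd-Warshall on the dense adjacency matrix
diameter_brute <- function(graph) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  D <- ifelse(A == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) {
    D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  }
  max(D)
}

# connected Erdos-Renyi-ish test graph (retry until connected)
random_connected_graph <- function(n, p, seed) {
  with_seed <- get("with_seed", envir = asNamespace("hemlink"))
  with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(g) && igraph::ecount(g) >= 3) return(g)
    }
  })
}

random_graph <- function(n, p, seed) {
  get("with_seed", envir = asNamespace("hemlink"))(
    seed, igraph::sample_gnp(n, p))
}

edge_set <- function(graph) {
  el <- igraph::as_edgelist(graph)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}

# named score lookup from a pair_scores frame
ps_get <- function(ps, a, b) {
  hit <- (ps$from == a & ps$to == b) | (ps$from == b & ps$to == a)
  ps$score[hit][1]
}

# tiny named graphs used across tests
graph_triangle <- function() igraph::make_graph(~ a - b, b - c, c - a)
graph_path3 <- function() igraph::make_graph(~ a - b, b - c)
graph_fig_branch <- function() igraph::make_graph(~ x - z, z - y, z - w)
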