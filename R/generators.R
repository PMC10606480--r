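#' Random regular graph
#'
#' Samples a simple undirected graph in which every node has degree `d`
#' (configuration-model style sampling via [igraph::sample_k_regular()]).
#' Deterministic for a given `seed`.
#'
#' @param n Number of nodes.
#' @param d Degree of every node; `n * d` must be even and `d < n`.
#' @param seed Integer seed.
#' @return An igraph graph with `n` nodes and `n * d / 2` edges.
#' @export
gen_regular <- function(n, d, seed = 1L) {
  if (d >= n) stop("degree d must be smaller than n")
  if ((n * d) %% 2 != 0) stop("n * d must be even for a d-regular graph")
  with_seed(seed, igraph::sample_k_regular(n, d, directed = FALSE,
                                           multiple = FALSE))
}

#' Barabasi-Albert scale-free graph
#'
#' Growth with preferential attachment: starting from a complete graph on
#' `m + 1` nodes, each arriving node attaches `m` distinct edges to existing
#' nodes drawn without replacement with probability proportional to their
#' current degree. The final edge count is exactly
#' `(m + 1) * m / 2 + (n - m - 1) * m`.
#'
#' @param n Number of nodes; `n > m`.
#' @param m Edges added per arriving node, `m >= 1`.
#' @param seed Integer seed.
#' @return An igraph graph on `n` nodes.
#' @export
gen_ba <- function(n, m, seed = 1L) {
  if (m < 1L) stop("m must be >= 1")
  if (m >= n) stop("m must be smaller than n")
  with_seed(seed, {
    n0 <- m + 1L
    seed_pairs <- t(utils::combn(n0, 2L))
    deg <- numeric(n)
    deg[1:n0] <- m
    from <- integer(0); to <- integer(0)
    for (v in seq.int(n0 + 1L, length.out = n - n0)) {
      existing <- seq_len(v - 1L)
      # successive weighted draws == redraw-on-repeat preferential attachment
      targets <- sample(existing, m, replace = FALSE, prob = deg[existing])
      from <- c(from, rep.int(v, m)); to <- c(to, targets)
      deg[targets] <- deg[targets] + 1
      deg[v] <- m
    }
    el <- rbind(seed_pairs, cbind(from, to))
    igraph::graph_from_edgelist(unname(el), directed = FALSE) |>
      add_missing_vertices(n)
  })
}

#' Watts-Strogatz small-world graph
#'
#' Starts from a ring lattice in which each node is tied to its `K / 2`
#' nearest neighbours on each side, then visits every lattice edge once and
#' with probability `p` rewires its far endpoint to a uniformly chosen node,
#' rejecting self-loops and duplicates (up to `n` retries per edge, after
#' which the edge is left in place). The edge count is always `n * K / 2`;
#' `p = 0` returns the ring lattice unchanged.
#'
#' @param n Number of nodes.
#' @param K Even ring degree, `K < n`.
#' @param p Rewiring probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return An igraph graph with `n * K / 2` edges.
#' @export
gen_ws <- function(n, K, p, seed = 1L) {
  check_ring_params(n, K, p)
  with_seed(seed, {
    el <- ring_lattice_edges(n, K)
    adj <- adjacency_sets(el, n)
    for (e in seq_len(nrow(el))) {
      if (runif(1) >= p) next
      u <- el[e, 1L]; v <- el[e, 2L]
      for (try in seq_len(n)) {
        w <- sample.int(n, 1L)
        if (w != u && !(w %in% adj[[u]])) {
          adj[[u]] <- c(setdiff(adj[[u]], v), w)
          adj[[v]] <- setdiff(adj[[v]], u)
          adj[[w]] <- c(adj[[w]], u)
          el[e, ] <- c(u, w)
          break
        }
      }
    }
    igraph::graph_from_edgelist(el, directed = FALSE) |>
      add_missing_vertices(n)
  })
}

#' Newman-Watts small-world graph
#'
#' Like [gen_ws()] but never removes lattice edges: for each lattice edge,
#' with probability `p` an additional shortcut is added from its first
#' endpoint to a uniformly chosen node (self-loops and duplicates rejected,
#' up to `n` retries). The ring lattice is always a subgraph of the result.
#'
#' @inheritParams gen_ws
#' @param p Shortcut-addition probability in `[0, 1]`.
#' @return An igraph graph with at least `n * K / 2` edges.
#' @export
gen_nw <- function(n, K, p, seed = 1L) {
  check_ring_params(n, K, p)
  with_seed(seed, {
    el <- ring_lattice_edges(n, K)
    adj <- adjacency_sets(el, n)
    extra <- matrix(0L, 0L, 2L)
    for (e in seq_len(nrow(el))) {
      if (runif(1) >= p) next
      u <- el[e, 1L]
      for (try in seq_len(n)) {
        w <- sample.int(n, 1L)
        if (w != u && !(w %in% adj[[u]])) {
          adj[[u]] <- c(adj[[u]], w)
          adj[[w]] <- c(adj[[w]], u)
          extra <- rbind(extra, c(u, w))
          break
        }
      }
    }
    igraph::graph_from_edgelist(rbind(el, extra), directed = FALSE) |>
      add_missing_vertices(n)
  })
}

check_ring_params <- function(n, K, p) {
  if (K %% 2 != 0) stop("ring degree K must be even")
  if (K >= n) stop("K must be smaller than n")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  invisible(TRUE)
}

ring_lattice_edges <- function(n, K) {
  half <- K %/% 2L
  from <- rep(seq_len(n), each = half)
  off <- rep(seq_len(half), times = n)
  to <- ((from - 1L + off) %% n) + 1L
  cbind(from, to)
}

adjacency_sets <- function(el, n) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1L]; v <- el[e, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

add_missing_vertices <- function(g, n) {
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

# Run code under a local RNG state so generators are seeded and side-effect
# free with respect to the caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}
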