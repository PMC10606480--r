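#' @importFrom Matrix Diagonal t crossprod
NULL

# ---- internal: adjacency, degrees, pair handling -------------------------

adjacency <- function(graph) {
  methods::as(igraph::as_adjacency_matrix(graph, sparse = TRUE), "dMatrix")
}

# degree clamp used by reg/dfpa/hem: k-hat = max(k, 1) so that probe pairs
# isolated by cross-validation remain scoreable
clamped_degree <- function(graph) pmax(igraph::degree(graph), 1)

# Normalise a pair specification into a 2-column integer index matrix.
# Accepts a 2-column matrix/data.frame of vertex names or indices, or NULL
# meaning all unordered pairs.
as_pair_index <- function(graph, pairs) {
  n <- igraph::vcount(graph)
  if (is.null(pairs)) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(cbind(idx[, 1L], idx[, 2L]))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  if (is.character(pairs)) {
    lab <- vertex_labels(graph)
    m <- matrix(match(pairs, lab), ncol = 2L)
    if (anyNA(m)) stop("unknown vertex label in pairs")
    pairs <- m
  }
  storage.mode(pairs) <- "integer"
  if (any(pairs < 1L) || any(pairs > n)) stop("vertex index out of range")
  if (any(pairs[, 1L] == pairs[, 2L])) stop("self-pairs are not scoreable")
  pairs
}

pair_scores <- function(graph, pairs, score, config) {
  lab <- vertex_labels(graph)
  out <- data.frame(from = lab[pairs[, 1L]], to = lab[pairs[, 2L]],
                    score = as.numeric(score), stringsAsFactors = FALSE)
  attr(out, "index_config") <- config
  class(out) <- c("pair_scores", "data.frame")
  out
}

matrix_at_pairs <- function(S, pairs) S[cbind(pairs[, 1L], pairs[, 2L])]

# ---- walk counts ---------------------------------------------------------

#' Walk counts from adjacency-matrix powers
#'
#' `A^k[x, y]` counts walks of length `k` between `x` and `y`; walks may
#' revisit edges (round trips), which is deliberate in the `lw` index.
#' Powers are computed by repeated sparse multiplication; entries are exact
#' integers as long as they stay below 2^53.
#'
#' @param graph An undirected simple igraph graph.
#' @param orders Integer vector of walk lengths (>= 1).
#' @return A named list of sparse matrices, one per requested order.
#' @export
walk_counts <- function(graph, orders) {
  orders <- sort(unique(as.integer(orders)))
  if (any(orders < 1L)) stop("walk orders must be >= 1")
  walk_powers(adjacency(graph), max(orders))[orders]
}

# all powers A^1..A^kmax as a list (shared across indices within a fold)
walk_powers <- function(A, kmax) {
  out <- vector("list", kmax)
  out[[1L]] <- A
  P <- A
  for (k in seq_len(kmax - 1L) + 1L) {
    P <- P %*% A
    if (length(P@x) && max(P@x) > 2^53) {
      stop("walk counts exceed exactly representable integers; ",
           "use a smaller order k")
    }
    out[[k]] <- P
  }
  names(out) <- paste0("A", seq_len(kmax))
  out
}

# ---- full score matrices (internal engine) -------------------------------

# Compute an n x n score matrix for one index on the (training) graph.
# `powers` optionally carries precomputed walk_powers(A, kmax) for reuse.
score_matrix <- function(graph, config, powers = NULL) {
  name <- config$name
  n <- igraph::vcount(graph)
  deg <- igraph::degree(graph)
  need_pow <- function(kmax) {
    if (is.null(powers) || length(powers) < kmax) {
      walk_powers(adjacency(graph), kmax)
    } else powers
  }
  switch(
    name,
    cn = as.matrix(need_pow(2L)[[2L]]),
    salton = {
      cn <- as.matrix(need_pow(2L)[[2L]])
      s <- sqrt(outer(deg, deg))
      out <- cn / s
      out[s == 0] <- 0
      out
    },
    ra = {
      A <- adjacency(graph)
      w <- ifelse(deg > 0, 1 / deg, 0)
      as.matrix(A %*% Diagonal(x = w) %*% A)
    },
    pa = outer(deg, deg),
    ch = ch_matrix(graph),
    reg = { kh <- pmax(deg, 1); outer(1 / kh, 1 / kh) },
    dfpa = {
      kh <- pmax(deg, 1)
      outer(kh, kh, pmax) / outer(kh, kh, pmin)
    },
    lw = {
      k <- config$k
      pw <- need_pow(k + 1L)
      as.matrix(pw[[k]] + pw[[k + 1L]])
    },
    lpk = {
      k <- config$k
      pw <- need_pow(k + 1L)
      S <- pw[[2L]]
      for (j in seq.int(3L, k + 1L)) S <- S + pw[[j]]
      as.matrix(S)
    },
    lp = {
      nmax <- config$n_order
      eps <- config$epsilon
      pw <- need_pow(nmax)
      S <- pw[[2L]]
      if (nmax >= 3L) {
        for (j in seq.int(3L, nmax)) S <- S + eps^(j - 2L) * pw[[j]]
      }
      as.matrix(S)
    },
    katz = katz_matrix(graph, config$beta),
    lo = lo_matrix(graph, config$alpha_lo),
    hem = {
      reg <- score_matrix(graph, list(name = "reg"))
      dfpa <- score_matrix(graph, list(name = "dfpa"))
      lw <- score_matrix(graph, list(name = "lw", k = config$k), powers)
      reg^config$alpha * dfpa^(1 - config$alpha) * lw
    },
    stop("unknown index: ", name)
  )
}

ch_matrix <- function(graph) {
  n <- igraph::vcount(graph)
  deg <- igraph::degree(graph)
  A <- adjacency(graph)
  nbr <- igraph::adjacent_vertices(graph, seq_len(n))
  nbr <- lapply(nbr, as.integer)
  CN <- methods::as(crossprod(A), "TsparseMatrix")  # A^2: common-neighbour counts
  out <- matrix(0, n, n)
  ii <- CN@i + 1L; jj <- CN@j + 1L
  sel <- ii < jj
  ii <- ii[sel]; jj <- jj[sel]
  for (t in seq_along(ii)) {
    x <- ii[t]; y <- jj[t]
    cns <- intersect(nbr[[x]], nbr[[y]])
    cns <- cns[cns != x & cns != y]
    if (!length(cns)) next
    s <- 0
    for (z in cns) {
      kzi <- sum(nbr[[z]] %in% cns)           # links to other common neighbours
      kze <- deg[z] - 2L - kzi                # links outside {x,y} and CN set
      s <- s + (1 + kzi) / (1 + kze)
    }
    out[x, y] <- s; out[y, x] <- s
  }
  out
}

katz_matrix <- function(graph, beta) {
  A <- adjacency(graph)
  lmax <- spectral_radius(A)
  if (lmax > 0 && beta >= 1 / lmax) {
    stop("beta must be below 1/lambda_max = ", format(1 / lmax),
         " for the Katz series to converge")
  }
  n <- nrow(A)
  S <- solve(diag(n) - beta * as.matrix(A)) - diag(n)
  (S + t(S)) / 2
}

lo_matrix <- function(graph, alpha_lo) {
  A <- as.matrix(adjacency(graph))
  M <- crossprod(A)                      # A^T A (= A^2 for symmetric A)
  Z <- tryCatch(solve(alpha_lo * M + diag(nrow(A)), M),
                error = function(e) stop(
                  "linear-optimization solve failed (", conditionMessage(e),
                  "); try a smaller damping alpha"))
  S <- alpha_lo * A %*% Z
  (S + t(S)) / 2
}

# dominant eigenvalue by power iteration (A symmetric nonnegative)
spectral_radius <- function(A, iter = 100L, tol = 1e-10) {
  n <- nrow(A)
  if (n == 0L || length(A@x) == 0L) return(0)
  x <- rep(1 / sqrt(n), n)
  lam <- 0
  for (i in seq_len(iter)) {
    y <- as.numeric(A %*% x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(0)
    y <- y / ny
    lam_new <- sum(y * as.numeric(A %*% y))
    if (abs(lam_new - lam) < tol) return(lam_new)
    lam <- lam_new
    x <- y
  }
  lam
}

# ---- exported pair-wise scorers ------------------------------------------

#' Local similarity indices
#'
#' Scores node pairs with one of the neighbourhood-based indices:
#' common neighbours (`cn`), Salton/cosine (`salton`), resource allocation
#' (`ra`), Cannistraci-Hebb (`ch`) or preferential attachment (`pa`).
#' All are computed from the graph passed in (in cross-validation, the
#' training graph).
#'
#' @param graph An undirected simple igraph graph.
#' @param pairs 2-column matrix of vertex names or indices, or `NULL` for
#'   all unordered pairs.
#' @param name One of `"cn"`, `"salton"`, `"ra"`, `"ch"`, `"pa"`.
#' @return A `pair_scores` data frame with columns `from`, `to`, `score`.
#' @export
score_local <- function(graph, pairs = NULL, name = c("cn", "salton", "ra",
                                                      "ch", "pa")) {
  name <- match.arg(name)
  p <- as_pair_index(graph, pairs)
  S <- score_matrix(graph, list(name = name))
  pair_scores(graph, p, matrix_at_pairs(S, p), list(name = name))
}

#' Regular-network index (degree balancing)
#'
#' `S = 1 / (k_x * k_y)` with the clamp `k -> max(k, 1)` so zero-degree
#' nodes (possible after probe removal) remain scoreable. Favors low-degree
#' pairs, the connection pattern of a random regular network under edge
#' deletion.
#'
#' @inheritParams score_local
#' @return A `pair_scores` data frame.
#' @export
score_reg <- function(graph, pairs = NULL) {
  p <- as_pair_index(graph, pairs)
  kh <- clamped_degree(graph)
  pair_scores(graph, p, 1 / (kh[p[, 1L]] * kh[p[, 2L]]), list(name = "reg"))
}

#' Difference-preferential-attachment index
#'
#' `S = max(k_x, k_y) / min(k_x, k_y)` (degrees clamped at 1): favors
#' connections between high- and low-degree nodes, the disassortative
#' mixing pattern of growing scale-free networks.
#'
#' @inheritParams score_local
#' @return A `pair_scores` data frame.
#' @export
score_dfpa <- function(graph, pairs = NULL) {
  p <- as_pair_index(graph, pairs)
  kh <- clamped_degree(graph)
  a <- kh[p[, 1L]]; b <- kh[p[, 2L]]
  pair_scores(graph, p, pmax(a, b) / pmin(a, b), list(name = "dfpa"))
}

#' Local-world walk index
#'
#' `S = (A^k + A^(k+1))_xy`: walks of length `k` and `k + 1` (both parities)
#' between the endpoints. `k` sets the breadth of structural information.
#'
#' @inheritParams score_local
#' @param k Walk-range parameter, integer `>= 2`.
#' @return A `pair_scores` data frame.
#' @export
score_lw <- function(graph, pairs = NULL, k = 2L) {
  if (k < 2L) stop("k must be >= 2")
  p <- as_pair_index(graph, pairs)
  S <- score_matrix(graph, list(name = "lw", k = as.integer(k)))
  pair_scores(graph, p, matrix_at_pairs(S, p), list(name = "lw", k = k))
}

#' Cumulative walk index (LP with unit weight)
#'
#' `S = (A^2 + A^3 + ... + A^(k+1))_xy`; the local-path index with its decay
#' parameter set to 1 and maximum order `k + 1`.
#'
#' @inheritParams score_lw
#' @return A `pair_scores` data frame.
#' @export
score_lpk <- function(graph, pairs = NULL, k = 2L) {
  if (k < 2L) stop("k must be >= 2")
  p <- as_pair_index(graph, pairs)
  S <- score_matrix(graph, list(name = "lpk", k = as.integer(k)))
  pair_scores(graph, p, matrix_at_pairs(S, p), list(name = "lpk", k = k))
}

#' Local-path index
#'
#' `S = (A^2 + eps*A^3 + ... + eps^(n-2)*A^n)_xy`. With `epsilon = 0` this
#' reduces to common neighbours; with `epsilon = 1` and `n = k + 1` it
#' equals [score_lpk()].
#'
#' @inheritParams score_local
#' @param epsilon Decay weight of higher-order walks.
#' @param n_order Maximum walk order, `>= 3`.
#' @return A `pair_scores` data frame.
#' @export
score_lp <- function(graph, pairs = NULL, epsilon = 0.01, n_order = 3L) {
  if (n_order < 3L) stop("n_order must be >= 3")
  p <- as_pair_index(graph, pairs)
  S <- score_matrix(graph, list(name = "lp", epsilon = epsilon,
                                n_order = as.integer(n_order)))
  pair_scores(graph, p, matrix_at_pairs(S, p),
              list(name = "lp", epsilon = epsilon, n_order = n_order))
}

#' Katz index
#'
#' `S = ((I - beta*A)^(-1) - I)_xy`, the exponentially damped sum of walks
#' of all lengths; `beta` must stay below `1/lambda_max(A)` (checked by
#' power iteration).
#'
#' @inheritParams score_local
#' @param beta Damping factor (default 0.01).
#' @return A `pair_scores` data frame.
#' @export
score_katz <- function(graph, pairs = NULL, beta = 0.01) {
  p <- as_pair_index(graph, pairs)
  S <- score_matrix(graph, list(name = "katz", beta = beta))
  pair_scores(graph, p, matrix_at_pairs(S, p), list(name = "katz", beta = beta))
}

#' Linear-optimization index
#'
#' `S = alpha * A (alpha * A'A + I)^(-1) A'A`, equal to the alternating
#' series `alpha*A^3 - alpha^2*A^5 + ...`; for small `alpha` it approaches
#' `alpha * A^3`.
#'
#' @inheritParams score_local
#' @param alpha_lo Damping factor (default 0.01).
#' @return A `pair_scores` data frame.
#' @export
score_lo <- function(graph, pairs = NULL, alpha_lo = 0.01) {
  if (alpha_lo <= 0) stop("alpha_lo must be positive")
  p <- as_pair_index(graph, pairs)
  S <- score_matrix(graph, list(name = "lo", alpha_lo = alpha_lo))
  pair_scores(graph, p, matrix_at_pairs(S, p),
              list(name = "lo", alpha_lo = alpha_lo))
}

#' @export
print.pair_scores <- function(x, ...) {
  cfg <- attr(x, "index_config")
  cat(sprintf("<pair_scores: %s index, %d pairs>\n",
              toupper(cfg$name), nrow(x)))
  print.data.frame(head(x, 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
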