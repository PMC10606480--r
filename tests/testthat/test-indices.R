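# Worked examples on explicit small graphs, oracle checks for walk counts
# and the global indices, and cross-index invariants.

test_that("local indices match hand-computed values on small graphs", {
  tri <- graph_triangle()
  expect_equal(ps_get(score_local(tri, NULL, "cn"), "a", "b"), 1)
  expect_equal(ps_get(score_local(tri, NULL, "salton"), "a", "b"), 0.5)
  expect_equal(ps_get(score_local(tri, NULL, "ra"), "a", "b"), 0.5)
  expect_equal(ps_get(score_local(tri, NULL, "pa"), "a", "b"), 4)
  expect_equal(ps_get(score_local(tri, NULL, "ch"), "a", "b"), 1)
  p3 <- graph_path3()
  expect_equal(ps_get(score_local(p3, NULL, "cn"), "a", "c"), 1)
  expect_equal(ps_get(score_local(p3, NULL, "salton"), "a", "c"), 1)
  expect_equal(ps_get(score_local(p3, NULL, "ra"), "a", "c"), 0.5)
  expect_equal(ps_get(score_local(p3, NULL, "pa"), "a", "c"), 1)
  expect_equal(ps_get(score_local(p3, NULL, "ch"), "a", "c"), 1)
})

test_that("Cannistraci-Hebb splits neighbour links into internal and external", {
  g <- igraph::make_graph(~ x - z1, x - z2, y - z1, y - z2, z1 - z2, z1 - w)
  # z1: one internal link (to z2), one external (to w) -> (1+1)/(1+1)
  # z2: one internal link (to z1), none external     -> (1+1)/(1+0)
  expect_equal(ps_get(score_local(g, rbind(c("x", "y")), "ch"), "x", "y"), 3)
})

test_that("degree-balancing index uses training degrees with the zero clamp", {
  g <- igraph::make_graph(~ a - b, a - c) # deg a=2, b=c=1
  expect_equal(ps_get(score_reg(g), "b", "c"), 1)
  expect_equal(ps_get(score_reg(g), "a", "b"), 0.5)
  iso <- igraph::add_vertices(igraph::make_star(6, mode = "undirected"), 1)
  igraph::V(iso)$name <- c("hub", paste0("l", 1:5), "orphan")
  # orphan has degree 0: clamped to 1, so score against the hub is 1/5
  expect_equal(ps_get(score_reg(iso), "orphan", "hub"), 1 / 5)
  # every pair of a d-regular graph scores 1/d^2
  gr <- gen_regular(20, 3, seed = 4)
  expect_true(all(abs(score_reg(gr)$score - 1 / 9) < 1e-15))
})

test_that("difference-preferential attachment scores degree ratios", {
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("l", 1:4))
  s <- score_dfpa(star)
  expect_equal(ps_get(s, "hub", "l1"), 4)
  expect_equal(ps_get(s, "l2", "l3"), 1)  # equal degrees: floor value 1
  g <- igraph::make_graph(~ a - b)
  g <- igraph::add_vertices(g, 0)
  expect_equal(score_dfpa(g, rbind(c("a", "b")))$score, 1)
})

test_that("walk counts equal exhaustive enumeration on small random graphs", {
  fig <- graph_fig_branch()
  wc <- walk_counts(fig, 2:5)
  i <- match(c("x", "y"), igraph::V(fig)$name)
  got <- vapply(wc, function(A) A[i[1], i[2]], 1)
  expect_equal(unname(got), c(1, 0, 3, 0))  # round trips on the branch
  for (s in 1:12) {
    g <- random_graph(4 + (s %% 7), 0.4, seed = 200 + s)
    if (igraph::ecount(g) == 0) next
    wc <- walk_counts(g, 2:6)
    n <- igraph::vcount(g)
    for (probe in list(c(1, 2), c(1, n), c(2, n %/% 2 + 1))) {
      for (k in 2:6) {
        expect_equal(wc[[paste0("A", k)]][probe[1], probe[2]],
                     walks_brute(g, probe[1], probe[2], k))
      }
    }
  }
  # closed 2-walks count the degree
  g <- random_connected_graph(12, 0.3, seed = 5)
  expect_equal(Matrix::diag(walk_counts(g, 2)[[1]]),
               unname(igraph::degree(g)))
})

test_that("walk-range indices follow their defining sums", {
  tri <- graph_triangle()
  expect_equal(ps_get(score_lw(tri, k = 2), "a", "b"), 4)  # A2 + A3 = 1 + 3
  fig <- graph_fig_branch()
  expect_equal(ps_get(score_lw(fig, k = 2), "x", "y"), 1)
  expect_equal(ps_get(score_lpk(fig, k = 4), "x", "y"), 4)
  # two nodes in different components never accumulate walks
  two <- igraph::make_graph(~ a - b, c - d)
  expect_equal(ps_get(score_lw(two, k = 3), "a", "c"), 0)
  # LPK(2) == LW(2); LP with eps = 1, n = k+1 == LPK(k); LP eps = 0 == CN
  g <- random_connected_graph(15, 0.25, seed = 31)
  expect_equal(score_lpk(g, k = 2)$score, score_lw(g, k = 2)$score)
  expect_equal(score_lp(g, epsilon = 1, n_order = 5)$score,
               score_lpk(g, k = 4)$score)
  expect_equal(score_lp(g, epsilon = 0, n_order = 4)$score,
               score_local(g, name = "cn")$score)
  # single 3-walk a-b-c-d weighted by eps
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  expect_equal(ps_get(score_lp(p4, epsilon = 0.5, n_order = 3), "a", "d"), 0.5)
})

test_that("Katz agrees with its truncated series and rejects divergence", {
  edge <- igraph::make_graph(~ a - b)
  s <- ps_get(score_katz(edge, beta = 0.1), "a", "b")
  expect_equal(s, 0.1 / (1 - 0.01), tolerance = 1e-12)  # geometric series
  p3 <- graph_path3()
  A <- as.matrix(igraph::as_adjacency_matrix(p3))
  series <- matrix(0, 3, 3); P <- diag(3)
  for (k in 1:50) { P <- P %*% A; series <- series + 0.1^k * P }
  i <- match(c("a", "c"), igraph::V(p3)$name)
  expect_equal(ps_get(score_katz(p3, beta = 0.1), "a", "c"),
               unname(series[i[1], i[2]]), tolerance = 1e-10)
  # leading order: S / beta^2 -> A^2 off-diagonal
  b <- 1e-5
  expect_equal(ps_get(score_katz(p3, beta = b), "a", "c") / b^2, 1,
               tolerance = 1e-4)
  # triangle has lambda_max = 2: beta >= 0.5 must be refused
  expect_error(score_katz(graph_triangle(), beta = 0.6), "converge")
})

test_that("linear-optimization index matches its alternating series", {
  tri <- graph_triangle()
  A <- as.matrix(igraph::as_adjacency_matrix(tri))
  a <- 0.01
  # sum the series to numerical convergence
  series <- matrix(0, 3, 3); term <- A %*% A %*% A; sgn <- 1; coef <- a
  for (j in 1:30) {
    series <- series + sgn * coef * term
    term <- term %*% A %*% A; sgn <- -sgn; coef <- coef * a
  }
  i <- match(c("a", "b"), igraph::V(tri)$name)
  expect_equal(ps_get(score_lo(tri, alpha_lo = a), "a", "b"),
               series[i[1], i[2]], tolerance = 1e-10)
  # alpha -> 0 limit: S / alpha -> A^3
  a0 <- 1e-6
  A3 <- (A %*% A %*% A)[i[1], i[2]]
  expect_equal(ps_get(score_lo(tri, alpha_lo = a0), "a", "b") / a0, A3,
               tolerance = 1e-4)
  empty <- igraph::make_empty_graph(4, directed = FALSE)
  expect_true(all(score_lo(empty)$score == 0))
})

test_that("all indices are symmetric, finite and (except LO) non-negative", {
  scorers <- list(
    function(g, p) score_local(g, p, "cn"),
    function(g, p) score_local(g, p, "salton"),
    function(g, p) score_local(g, p, "ra"),
    function(g, p) score_local(g, p, "ch"),
    function(g, p) score_local(g, p, "pa"),
    score_reg, score_dfpa,
    function(g, p) score_lw(g, p, k = 3),
    function(g, p) score_lpk(g, p, k = 3),
    function(g, p) score_lp(g, p, epsilon = 0.3, n_order = 4),
    function(g, p) score_katz(g, p, beta = 0.05),
    function(g, p) score_hem(g, p, alpha = 0.3, k = 2))
  for (s in 1:4) {
    g <- random_connected_graph(12, 0.3, seed = 400 + s)
    n <- igraph::vcount(g)
    set.seed(500 + s)
    pr <- cbind(sample(n, 25, replace = TRUE), sample(n, 25, replace = TRUE))
    pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
    for (fn in scorers) {
      fwd <- fn(g, pr)$score
      rev <- fn(g, pr[, 2:1])$score
      expect_equal(fwd, rev, tolerance = 1e-12)
      expect_true(all(fwd >= 0))
      expect_true(all(is.finite(fwd)))
    }
    # the linear-optimization form alpha*lambda^3 / (1 + alpha*lambda^2) is
    # signed on negative eigenvalues: symmetry and boundedness only
    lo_f <- score_lo(g, pr, alpha_lo = 0.01)$score
    expect_equal(lo_f, score_lo(g, pr[, 2:1], alpha_lo = 0.01)$score,
                 tolerance = 1e-12)
    expect_true(all(is.finite(lo_f)))
    expect_gt(min(lo_f), -1)  # magnitude bounded by the damped spectrum
  }
})

test_that("on regular graphs CN, Salton and RA are rank-equivalent", {
  g <- gen_regular(40, 5, seed = 6)
  cn <- score_local(g, name = "cn")$score
  expect_equal(score_local(g, name = "salton")$score, cn / 5)
  expect_equal(score_local(g, name = "ra")$score, cn / 5)
})
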