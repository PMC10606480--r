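test_that("k-fold edge splits partition the edge set evenly", {
  g <- gen_regular(60, 3, seed = 2)  # 90 edges
  sp <- kfold_edges(g, folds = 10, seed = 1)
  expect_length(sp, 10L)
  sizes <- vapply(sp, function(f) nrow(f$probe), 1L)
  expect_true(all(sizes == 9L))
  key <- function(m) {
    a <- as.numeric(m[, 1]); b <- as.numeric(m[, 2])
    paste(pmin(a, b), pmax(a, b), sep = "|")
  }
  probes <- lapply(sp, function(f) key(f$probe))
  expect_equal(sum(lengths(probes)), igraph::ecount(g))
  expect_setequal(unlist(probes), edge_set(g))       # union == E
  expect_equal(anyDuplicated(unlist(probes)), 0L)    # pairwise disjoint
  for (f in sp) {
    expect_setequal(c(key(f$train), key(f$probe)), edge_set(g))
  }
  expect_identical(kfold_edges(g, 10, seed = 7), kfold_edges(g, 10, seed = 7))
  expect_error(kfold_edges(g, 1, seed = 1), "folds")
  expect_error(kfold_edges(g, 1000, seed = 1), "folds")
})

test_that("AUC follows the comparison-count arithmetic", {
  # one probe score against ten nonexistent: 7 smaller, 2 tied, 1 larger
  r <- auc_score(5, c(1, 1, 2, 2, 3, 3, 4, 5, 5, 9))
  expect_equal(r$n1, 7); expect_equal(r$n2, 2); expect_equal(r$n, 10)
  expect_equal(r$auc, 0.8)
  # perfect separation and complete ties
  expect_equal(auc_score(c(5, 6), runif(50))$auc, 1)
  expect_equal(auc_score(rep(1, 5), rep(1, 40))$auc, 0.5)
  # degenerate inputs
  expect_error(auc_score(numeric(0), 1:5), "empty")
  expect_error(auc_score(1:5, numeric(0)), "complete graph")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(9)
  pos <- sample(1:20, 30, replace = TRUE)
  neg <- sample(1:20, 200, replace = TRUE)
  a1 <- auc_score(pos, neg)$auc
  a2 <- auc_score(exp(pos / 3), exp(neg / 3))$auc
  expect_equal(a1, a2)
})

test_that("sampled AUC approximates the exhaustive value", {
  set.seed(4)
  pos <- rnorm(40, mean = 0.5)
  neg <- rnorm(3000)
  ex <- auc_score(pos, neg)$auc
  sa <- auc_score(pos, neg, mode = "sample", n = 2e5, seed = 3)$auc
  expect_equal(sa, ex, tolerance = 0.01)
  # uniform random scores carry no signal
  expect_equal(auc_score(runif(500), runif(5000))$auc, 0.5, tolerance = 0.02)
})

test_that("precision@L counts probe edges in the deterministic top list", {
  # 30 probe members hold distinct top scores among 200 candidates
  sc <- c(seq(300, 271), runif(170, 0, 100))
  is_probe <- c(rep(TRUE, 30), rep(FALSE, 170))
  expect_equal(precision_at(sc, is_probe, L = 100), 0.30)
  expect_equal(precision_at(sc, is_probe, L = 30), 1)
  # all tied: the lexicographic prefix decides
  expect_equal(precision_at(rep(1, 10), c(TRUE, TRUE, rep(FALSE, 8)), L = 2), 1)
  expect_equal(precision_at(rep(1, 10), c(rep(FALSE, 8), TRUE, TRUE), L = 2), 0)
  # explicit pair tie-break: reversed pair order flips the outcome
  prs <- cbind(c(2, 1), c(3, 9))
  expect_equal(precision_at(c(1, 1), c(TRUE, FALSE), L = 1, pairs = prs), 0)
  expect_error(precision_at(1:3, rep(TRUE, 3), L = 5), "exceeds")
})

test_that("cross-validation is reproducible and degree-aware", {
  g <- gen_ws(150, 6, 0.2, seed = 8)
  r1 <- cross_validate(g, "cn", folds = 5, seed = 3, L = 20)
  r2 <- cross_validate(g, "cn", folds = 5, seed = 3, L = 20)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_true(all(r1$per_fold$auc >= 0 & r1$per_fold$auc <= 1))
  expect_true(r1$n1 + r1$n2 <= r1$n_comparisons)
  # removing probe edges strictly lowers total training degree
  sp <- kfold_edges(g, folds = 5, seed = 3)
  for (f in sp) {
    expect_equal(2 * nrow(f$train),
                 2 * igraph::ecount(g) - 2 * nrow(f$probe))
    expect_lt(nrow(f$train), igraph::ecount(g))
  }
})

test_that("shared-fold evaluation of an index list matches single runs", {
  g <- gen_ws(120, 4, 0.3, seed = 5)
  multi <- cross_validate(g, list("reg", list(name = "lw", k = 2)),
                          folds = 5, seed = 11, metrics = "auc")
  single <- cross_validate(g, "reg", folds = 5, seed = 11, metrics = "auc")
  expect_equal(multi$reg$mean_auc, single$mean_auc)
  expect_named(multi, c("reg", "lw2"))
})

test_that("sampled-mode cross-validation stays close to exhaustive", {
  g <- gen_ws(100, 4, 0.2, seed = 13)
  ex <- cross_validate(g, "lw", folds = 5, seed = 2, auc_mode = "exhaustive",
                       metrics = "auc")
  sa <- cross_validate(g, "lw", folds = 5, seed = 2, auc_mode = "sample",
                       auc_n = 2e5, metrics = "auc")
  expect_equal(sa$mean_auc, ex$mean_auc, tolerance = 0.01)
})
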