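# Cross-validated link-prediction evaluation: 10-fold edge splits, AUC by
# probe-vs-nonexistent comparison, and precision-at-L.

#' Index configuration
#'
#' Bundles an index name with its free parameters for use in
#' [cross_validate()] and [hem_grid_scan()]. Recognised names: `cn`,
#' `salton`, `ra`, `ch`, `pa`, `reg`, `dfpa`, `lw`, `lpk`, `lp`, `katz`,
#' `lo`, `hem`.
#'
#' @param name Index name.
#' @param k Walk range for `lw`/`lpk`/`hem` (integer >= 2).
#' @param alpha Mixing exponent in `[0, 1]` for `hem`.
#' @param epsilon Decay weight for `lp`.
#' @param n_order Maximum walk order for `lp`.
#' @param beta Katz damping.
#' @param alpha_lo Linear-optimization damping.
#' @return A list of class `index_config`.
#' @export
index_config <- function(name, k = NULL, alpha = NULL, epsilon = NULL,
                         n_order = NULL, beta = NULL, alpha_lo = NULL) {
  known <- c("cn", "salton", "ra", "ch", "pa", "reg", "dfpa", "lw", "lpk",
             "lp", "katz", "lo", "hem")
  if (!name %in% known) {
    stop("unknown index '", name, "'; expected one of: ",
         paste(known, collapse = ", "))
  }
  if (name %in% c("lw", "lpk")) {
    if (is.null(k)) k <- 2L
    if (k < 2L) stop("k must be >= 2")
  }
  if (name == "hem") {
    if (is.null(k)) k <- 2L
    if (is.null(alpha)) alpha <- 0.5
    if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
    if (k < 2L) stop("k must be >= 2")
  }
  if (name == "lp") {
    if (is.null(epsilon)) epsilon <- 0.01
    if (is.null(n_order)) n_order <- 3L
  }
  if (name == "katz" && is.null(beta)) beta <- 0.01
  if (name == "lo" && is.null(alpha_lo)) alpha_lo <- 0.01
  structure(list(name = name, k = if (!is.null(k)) as.integer(k),
                 alpha = alpha, epsilon = epsilon,
                 n_order = if (!is.null(n_order)) as.integer(n_order),
                 beta = beta, alpha_lo = alpha_lo),
            class = "index_config")
}

config_label <- function(cfg) {
  switch(cfg$name,
         lw = paste0("lw", cfg$k),
         lpk = paste0("lpk", cfg$k),
         hem = sprintf("hem_a%s_k%d", format(cfg$alpha), cfg$k),
         cfg$name)
}

# walk order needed by a config (0 = degrees only)
config_kmax <- function(cfg) {
  switch(cfg$name,
         cn = 2L, salton = 2L, ra = 0L, ch = 0L, pa = 0L, reg = 0L,
         dfpa = 0L, lw = cfg$k + 1L, lpk = cfg$k + 1L, lp = cfg$n_order,
         katz = 0L, lo = 0L, hem = cfg$k + 1L)
}

as_config <- function(x) {
  if (inherits(x, "index_config")) return(x)
  if (is.character(x) && length(x) == 1L) return(index_config(x))
  if (is.list(x) && !is.null(x$name)) return(do.call(index_config, x))
  stop("cannot interpret index specification")
}

fold_assignment <- function(m, folds, seed) {
  if (folds < 2L) stop("need at least 2 folds")
  if (folds > m) stop("more folds than edges")
  with_seed(seed, {
    fid <- integer(m)
    fid[sample.int(m)] <- rep(seq_len(folds), length.out = m)
    fid
  })
}

#' K-fold edge splits
#'
#' Shuffles the edge set by `seed` and partitions it into `folds` probe
#' sets of near-equal size (difference at most one edge); every edge is a
#' probe exactly once, and the union of probe sets is the full edge set.
#'
#' @param graph An undirected simple igraph graph.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list of `folds` splits, each a list with `fold`, `train` and
#'   `probe` (2-column matrices of vertex labels).
#' @export
kfold_edges <- function(graph, folds = 10L, seed = 1L) {
  m <- igraph::ecount(graph)
  fid <- fold_assignment(m, folds, seed)
  el <- igraph::as_edgelist(graph, names = FALSE)
  lab <- vertex_labels(graph)
  lapply(seq_len(folds), function(f) {
    pr <- fid == f
    list(fold = f,
         train = cbind(lab[el[!pr, 1L]], lab[el[!pr, 2L]]),
         probe = cbind(lab[el[pr, 1L]], lab[el[pr, 2L]]))
  })
}

#' AUC from probe and nonexistent-pair scores
#'
#' The probability that a randomly chosen probe (missing) link outscores a
#' randomly chosen nonexistent link, ties counting one half:
#' `AUC = (n1 + 0.5 * n2) / n`. In `"exhaustive"` mode every
#' probe-nonexistent pair is compared exactly (via a rank statistic); in
#' `"sample"` mode `n` independent comparisons are drawn.
#'
#' @param probe_scores Scores of the probe (test-set) pairs.
#' @param nonexistent_scores Scores of the nonexistent pairs (`U - E`).
#' @param mode `"exhaustive"` or `"sample"`.
#' @param n Number of sampled comparisons (sample mode).
#' @param seed Seed for sample mode.
#' @return A list with `auc`, `n1`, `n2` and `n`.
#' @export
auc_score <- function(probe_scores, nonexistent_scores,
                      mode = c("exhaustive", "sample"), n = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  if (!length(probe_scores)) stop("probe set is empty")
  if (!length(nonexistent_scores)) {
    stop("no nonexistent pairs to compare against (complete graph)")
  }
  if (mode == "exhaustive") {
    sn <- sort(nonexistent_scores, method = "radix")
    le <- findInterval(probe_scores, sn)
    lt <- findInterval(probe_scores, sn, left.open = TRUE)
    n1 <- sum(as.numeric(lt))
    n2 <- sum(as.numeric(le - lt))
    ntot <- as.numeric(length(probe_scores)) * length(nonexistent_scores)
  } else {
    draws <- with_seed(seed, list(
      ps = probe_scores[sample.int(length(probe_scores), n, replace = TRUE)],
      ns = nonexistent_scores[sample.int(length(nonexistent_scores), n,
                                         replace = TRUE)]))
    n1 <- sum(draws$ps > draws$ns)
    n2 <- sum(draws$ps == draws$ns)
    ntot <- n
  }
  list(auc = (n1 + 0.5 * n2) / ntot, n1 = n1, n2 = n2, n = ntot)
}

#' Precision at L
#'
#' Sorts all candidate (non-training) pairs by score, descending, with a
#' deterministic tie-break (score desc, then pair lexicographic asc), and
#' returns the fraction of the top `L` candidates that are probe edges.
#'
#' @param scores Candidate-pair scores.
#' @param is_probe Logical vector: is the candidate a probe edge?
#' @param L Length of the prediction list (default 100).
#' @param pairs Optional 2-column integer matrix of candidate endpoints
#'   used for the lexicographic tie-break; input order is used if absent.
#' @return Precision in `[0, 1]`.
#' @export
precision_at <- function(scores, is_probe, L = 100L, pairs = NULL) {
  ncand <- length(scores)
  if (L < 1L) stop("L must be >= 1")
  if (L > ncand) stop("L exceeds the number of candidate pairs")
  if (length(is_probe) != ncand) stop("scores and is_probe length mismatch")
  # restrict to the score range that can reach the top L, then break ties
  thr <- if (L < ncand) -sort(-scores, partial = L)[L] else min(scores)
  sel <- which(scores >= thr)
  if (is.null(pairs)) {
    ord <- sel[order(-scores[sel], sel)]
  } else {
    ord <- sel[order(-scores[sel], pairs[sel, 1L], pairs[sel, 2L])]
  }
  sum(is_probe[ord[seq_len(L)]]) / L
}

#' Cross-validated evaluation of link-prediction indices
#'
#' Runs k-fold edge cross-validation: for each fold the probe edges are
#' removed, every index is scored on the training graph (walk powers are
#' computed once per fold and shared across indices), and AUC and
#' precision-at-L are measured. AUC compares probe pairs against
#' nonexistent pairs (`U - E`); the precision candidate list is all
#' non-training pairs. In `auc_mode = "auto"`, comparisons are exhaustive
#' when the graph has at most `1e7` node pairs and sampled (`auc_n` draws)
#' otherwise.
#'
#' @param graph A connected undirected simple igraph graph.
#' @param index An [index_config()], an index name, or a list of either;
#'   a list evaluates all indices on identical fold splits.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling the edge shuffle (and sampling).
#' @param L Precision list length (default 100; clipped to the candidate
#'   count on very small graphs).
#' @param auc_mode `"auto"`, `"exhaustive"` or `"sample"`.
#' @param auc_n Comparisons per fold in sample mode.
#' @param metrics Character subset of `c("auc", "precision")`.
#' @return An `eval_result` (single index) or named list of them.
#' @export
cross_validate <- function(graph, index, folds = 10L, seed = 1L, L = 100L,
                           auc_mode = c("auto", "exhaustive", "sample"),
                           auc_n = 1e5, metrics = c("auc", "precision")) {
  auc_mode <- match.arg(auc_mode)
  single <- inherits(index, "index_config") ||
    (is.character(index) && length(index) == 1L) ||
    (is.list(index) && !is.null(index$name))
  configs <- if (single) list(as_config(index)) else lapply(index, as_config)
  res <- cv_engine(graph, configs, folds = folds, seed = seed, L = L,
                   auc_mode = auc_mode, auc_n = auc_n, metrics = metrics)
  if (single) res[[1L]] else res
}

cv_engine <- function(graph, configs, folds, seed, L, auc_mode, auc_n,
                      metrics) {
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  npairs <- n * (n - 1) / 2
  want_auc <- "auc" %in% metrics
  want_prec <- "precision" %in% metrics
  exhaustive <- switch(auc_mode, auto = npairs <= 1e7,
                       exhaustive = TRUE, sample = FALSE)
  el <- igraph::as_edgelist(graph, names = FALSE)
  ei <- pmin(el[, 1L], el[, 2L]); ej <- pmax(el[, 1L], el[, 2L])
  # column-major upper-triangle position of pair (i < j)
  edge_pos <- (ej - 1) * (ej - 2) / 2 + ei
  fid <- fold_assignment(m, folds, seed)
  kmax <- max(vapply(configs, config_kmax, 1L))
  labels <- vapply(configs, config_label, "")
  if (want_prec) {
    ui <- rep_pair_i(n); uj <- rep_pair_j(n)
  }
  per <- lapply(configs, function(cfg) {
    data.frame(fold = seq_len(folds), auc = NA_real_, precision = NA_real_,
               n1 = NA_real_, n2 = NA_real_, n = NA_real_)
  })
  for (f in seq_len(folds)) {
    probe <- which(fid == f)
    gt <- igraph::delete_edges(graph, probe)
    powers <- if (kmax >= 2L) walk_powers(adjacency(gt), kmax) else NULL
    is_edge <- logical(npairs); is_edge[edge_pos] <- TRUE
    is_probe_pos <- logical(npairs); is_probe_pos[edge_pos[probe]] <- TRUE
    cand <- which(!is_edge | is_probe_pos)   # non-training pairs
    probe_in_cand <- is_probe_pos[cand]
    Lf <- min(L, length(cand))
    for (ci in seq_along(configs)) {
      cfg <- configs[[ci]]
      S <- tryCatch(score_matrix(gt, cfg, powers), error = function(e) {
        stop("index '", labels[ci], "' failed on fold ", f, ": ",
             conditionMessage(e))
      })
      s_ut <- S[upper.tri(S)]
      if (want_auc) {
        a <- auc_score(s_ut[edge_pos[probe]], s_ut[!is_edge],
                       mode = if (exhaustive) "exhaustive" else "sample",
                       n = auc_n, seed = seed * 131L + f)
        per[[ci]][f, c("auc", "n1", "n2", "n")] <-
          c(a$auc, a$n1, a$n2, a$n)
      }
      if (want_prec) {
        per[[ci]][f, "precision"] <- precision_at(
          s_ut[cand], probe_in_cand, L = Lf,
          pairs = cbind(ui[cand], uj[cand]))
      }
    }
  }
  out <- lapply(seq_along(configs), function(ci) {
    d <- per[[ci]]
    structure(list(index = configs[[ci]],
                   per_fold = d,
                   mean_auc = if (want_auc) mean(d$auc) else NA_real_,
                   mean_precision = if (want_prec) mean(d$precision)
                                    else NA_real_,
                   n1 = sum(d$n1), n2 = sum(d$n2), n_comparisons = sum(d$n),
                   L = L, folds = folds, seed = seed),
              class = "eval_result")
  })
  names(out) <- labels
  out
}

# endpoint indices of all upper-triangle pairs in column-major order
rep_pair_i <- function(n) {
  unlist(lapply(seq_len(n)[-1L], function(j) seq_len(j - 1L)), use.names = FALSE)
}
rep_pair_j <- function(n) {
  rep.int(seq_len(n)[-1L], times = seq_len(n - 1L))
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result: %s, %d-fold CV>\n",
              toupper(config_label(x$index)), x$folds))
  cat(sprintf("  mean AUC = %.4f", x$mean_auc))
  if (!is.na(x$mean_precision)) {
    cat(sprintf("   mean precision@%d = %.4f", x$L, x$mean_precision))
  }
  cat("\n")
  invisible(x)
}
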