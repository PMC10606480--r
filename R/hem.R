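# The hybrid evolution-mechanism (HEM) index, its (alpha, k) grid scan and
# the two main-factor diagnostics.

#' Hybrid evolution-mechanism index
#'
#' `S = Reg^alpha * DFPA^(1 - alpha) * LW_k`: a multiplicative blend of the
#' degree-balancing index, the difference-preferential-attachment index and
#' the bounded walk-count index. `alpha` close to 1 favors regular-network
#' behaviour, close to 0 favors disassortative behaviour; `k` sets the walk
#' range. Pairs with no walk of length `k` or `k + 1` score 0.
#'
#' @inheritParams score_local
#' @param alpha Mixing exponent in `[0, 1]`.
#' @param k Walk-range parameter, integer `>= 2`.
#' @return A `pair_scores` data frame.
#' @export
score_hem <- function(graph, pairs = NULL, alpha = 0.5, k = 2L) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (k < 2L) stop("k must be >= 2")
  p <- as_pair_index(graph, pairs)
  kh <- clamped_degree(graph)
  a <- kh[p[, 1L]]; b <- kh[p[, 2L]]
  reg <- 1 / (a * b)
  dfpa <- pmax(a, b) / pmin(a, b)
  Slw <- score_matrix(graph, list(name = "lw", k = as.integer(k)))
  s <- reg^alpha * dfpa^(1 - alpha) * matrix_at_pairs(Slw, p)
  pair_scores(graph, p, s, list(name = "hem", alpha = alpha, k = k))
}

#' Scan the HEM parameter grid under cross-validation
#'
#' Evaluates the hybrid index for every `(alpha, k)` cell of the grid with
#' k-fold edge cross-validation, reusing identical fold splits (and walk
#' powers) across cells, and reports the best cell per metric. The default
#' grid is `alpha` in {0, 0.25, 0.5, 0.75, 1} by `k` in {2, 4, 8}
#' (15 cells).
#'
#' @inheritParams cross_validate
#' @param alphas Mixing exponents to scan.
#' @param ks Walk ranges to scan.
#' @return A `hem_grid`: list with `results` (data frame of `alpha`, `k`,
#'   `mean_auc`, `mean_precision`), `best_auc`, `best_precision`, `evals`
#'   (per-cell `eval_result`s), and the evaluation settings.
#' @export
hem_grid_scan <- function(graph, alphas = c(0, 0.25, 0.5, 0.75, 1),
                          ks = c(2L, 4L, 8L), folds = 10L, seed = 1L,
                          L = 100L, auc_mode = c("auto", "exhaustive",
                                                 "sample"),
                          auc_n = 1e5, metrics = c("auc", "precision")) {
  if (!length(alphas) || !length(ks)) stop("empty parameter grid")
  auc_mode <- match.arg(auc_mode)
  grid <- expand.grid(alpha = alphas, k = as.integer(ks),
                      KEEP.OUT.ATTRS = FALSE)
  configs <- lapply(seq_len(nrow(grid)), function(i) {
    index_config("hem", alpha = grid$alpha[i], k = grid$k[i])
  })
  evals <- cv_engine(graph, configs, folds = folds, seed = seed, L = L,
                     auc_mode = auc_mode, auc_n = auc_n, metrics = metrics)
  grid$mean_auc <- vapply(evals, function(e) e$mean_auc, 1)
  grid$mean_precision <- vapply(evals, function(e) e$mean_precision, 1)
  pick_best <- function(v) {
    if (all(is.na(v))) return(NULL)
    ord <- order(-v, grid$alpha, grid$k)
    as.list(grid[ord[1L], ])
  }
  structure(list(results = grid,
                 best_auc = pick_best(grid$mean_auc),
                 best_precision = pick_best(grid$mean_precision),
                 evals = evals, folds = folds, seed = seed, L = L),
            class = "hem_grid")
}

#' @export
print.hem_grid <- function(x, ...) {
  cat(sprintf("<hem_grid: %d cells, %d-fold CV>\n", nrow(x$results), x$folds))
  print(x$results, row.names = FALSE)
  if (!is.null(x$best_auc)) {
    cat(sprintf("best AUC %.4f at alpha = %s, k = %d\n",
                x$best_auc$mean_auc, format(x$best_auc$alpha), x$best_auc$k))
  }
  invisible(x)
}

hem_factors <- c("reg", "dfpa", "lw2", "lw4", "lw8")

#' Main factors, method 1: accuracy of individual factors
#'
#' Cross-validates each constituent factor of the hybrid index (Reg, DFPA,
#' LW2, LW4, LW8) separately and applies the selection rule of
#' [select_main_factors_m1()] to the mean AUCs.
#'
#' @inheritParams cross_validate
#' @return A list of class `factor_report` with `factor_auc` (named vector)
#'   and `main_factors`.
#' @export
factor_method1 <- function(graph, folds = 10L, seed = 1L,
                           auc_mode = c("auto", "exhaustive", "sample"),
                           auc_n = 1e5) {
  auc_mode <- match.arg(auc_mode)
  configs <- list(index_config("reg"), index_config("dfpa"),
                  index_config("lw", k = 2L), index_config("lw", k = 4L),
                  index_config("lw", k = 8L))
  evals <- cv_engine(graph, configs, folds = folds, seed = seed, L = 100L,
                     auc_mode = auc_mode, auc_n = auc_n, metrics = "auc")
  aucs <- setNames(vapply(evals, function(e) e$mean_auc, 1), hem_factors)
  structure(list(method = 1L, factor_auc = aucs,
                 main_factors = select_main_factors_m1(aucs)),
            class = "factor_report")
}

#' Method-1 selection rule
#'
#' Takes the two factors with the highest accuracy; if both are LW
#' variants, only the best LW factor is kept. Ties are broken by the fixed
#' factor order `reg, dfpa, lw2, lw4, lw8`.
#'
#' @param factor_auc Named numeric vector of factor accuracies with names
#'   among `reg`, `dfpa`, `lw2`, `lw4`, `lw8`.
#' @return Character vector of main-factor names.
#' @export
select_main_factors_m1 <- function(factor_auc) {
  if (is.null(names(factor_auc)) ||
      !all(names(factor_auc) %in% hem_factors)) {
    stop("factor_auc must be named with: ", paste(hem_factors, collapse = ", "))
  }
  ord <- order(-factor_auc, match(names(factor_auc), hem_factors))
  top2 <- names(factor_auc)[ord[1:2]]
  if (all(startsWith(top2, "lw"))) top2[1L] else top2
}

#' Main factors, method 2: aggregate the best parameter cells
#'
#' Takes the five grid cells with the highest mean accuracy, averages their
#' `alpha` (`alpha_star`) and takes the mode of their `k` (`k_star`;
#' smallest modal value on ties). The main-factor set is `LW(k_star)` plus
#' Reg when `alpha_star > 0.5`, DFPA when `alpha_star < 0.5`, and neither
#' when `alpha_star` equals 0.5 (within 1e-9, guarding float drift on the
#' 0.25-step grid).
#'
#' @param grid A [hem_grid_scan()] result, or a data frame with columns
#'   `alpha`, `k` and a metric column.
#' @param metric `"auc"` (default) or `"precision"`.
#' @return A list of class `factor_report` with `top5`, `alpha_star`,
#'   `k_star` and `main_factors`.
#' @export
factor_method2 <- function(grid, metric = c("auc", "precision")) {
  metric <- match.arg(metric)
  res <- if (inherits(grid, "hem_grid")) grid$results else as.data.frame(grid)
  mcol <- paste0("mean_", metric)
  if (!mcol %in% names(res)) {
    if (metric %in% names(res)) mcol <- metric
    else stop("grid lacks a '", mcol, "' column")
  }
  if (nrow(res) < 5L) stop("method 2 needs at least 5 grid cells")
  ord <- order(-res[[mcol]], res$alpha, res$k)
  top5 <- res[ord[1:5], c("alpha", "k", mcol)]
  alpha_star <- mean(top5$alpha)
  ks_u <- sort(unique(top5$k))
  counts <- vapply(ks_u, function(z) sum(top5$k == z), 1)
  k_star <- as.integer(ks_u[which.max(counts)])  # smallest modal k on ties
  main <- paste0("lw", k_star)
  if (alpha_star > 0.5 + 1e-9) main <- c("reg", main)
  else if (alpha_star < 0.5 - 1e-9) main <- c("dfpa", main)
  structure(list(method = 2L, top5 = top5, alpha_star = alpha_star,
                 k_star = k_star, main_factors = main),
            class = "factor_report")
}

#' @export
print.factor_report <- function(x, ...) {
  cat(sprintf("<factor_report: method %d>\n", x$method))
  if (x$method == 1L) {
    print(round(x$factor_auc, 4))
  } else {
    cat(sprintf("  alpha* = %s  k* = %d\n", format(x$alpha_star), x$k_star))
  }
  cat("  main factors:", paste(toupper(x$main_factors), collapse = ", "), "\n")
  invisible(x)
}
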