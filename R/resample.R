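#' Subnetwork edge masks
#'
#' Builds the eight subcortical edge masks over the canonical edge ordering:
#' `SUB-SUB` (both endpoints subcortical) and `SUB-X` for each of the seven
#' cortical networks (exactly one endpoint subcortical, the other in
#' network X). The masks in the family are pairwise disjoint.
#'
#' @param atlas atlas table with `node_id` and `network` columns.
#' @param edge_map edge ordering from [edge_map()].
#' @return named list of logical vectors over the edge map; edge counts are
#'   attached as attribute `counts`.
#' @examples
#' masks <- build_masks(make_atlas(1), edge_map(246))
#' sum(masks[["SUB-SUB"]])  # 36 * 35 / 2 = 630
#' @export
build_masks <- function(atlas, edge_map) {
  validate_atlas(atlas)
  check_that(any(atlas$network == "SUB"), "atlas has no SUB (subcortical) nodes")
  ord <- order(atlas$node_id)
  network <- atlas$network[ord]
  ni <- network[edge_map$i + 1L]
  nj <- network[edge_map$j + 1L]
  masks <- list("SUB-SUB" = ni == "SUB" & nj == "SUB")
  for (x in CORTICAL_NETWORKS) {
    masks[[paste0("SUB-", x)]] <-
      (ni == "SUB" & nj == x) | (ni == x & nj == "SUB")
  }
  attr(masks, "counts") <- vapply(masks, sum, integer(1))
  masks
}

# inner CV component selection used inside the resampling loop: returns the
# A (1..ncomp_max) minimizing assembled held-out squared error
inner_cv_ncomp <- function(X, Y, k = 5L, ncomp_max = 5L) {
  n <- nrow(X)
  k <- min(k, n)
  ncomp_max <- min(ncomp_max, ncol(X), n - ceiling(n / k) - 1L)
  if (ncomp_max < 1) return(1L)
  folds <- sample(rep(seq_len(k), length.out = n))
  press <- numeric(ncomp_max)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_plsr(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], ncomp_max)
    for (a in seq_len(ncomp_max)) {
      yh <- predict(fit, X[!tr, , drop = FALSE], ncomp = a)
      press[a] <- press[a] + sum((Y[!tr, , drop = FALSE] - yh)^2)
    }
  }
  which.min(press)
}

# mean per-outcome Pearson r between observed and predicted; outcomes whose
# prediction is degenerate (zero variance) contribute 0
mean_outcome_r <- function(Y, Y_hat) {
  mean(vapply(seq_len(ncol(Y)), function(j) {
    if (stats::sd(Y_hat[, j]) < 1e-12 || stats::sd(Y[, j]) < 1e-12) return(0)
    stats::cor(Y[, j], Y_hat[, j])
  }, numeric(1)))
}

#' Resampled model performance with a permuted-outcome null
#'
#' The 80/20 resampling framework: on each iteration the sample is split
#' into a training set (`train_frac`) and a test set; an inner k-fold
#' cross-validation on the training set chooses the component count; a
#' SIMPLS model is fitted and performance is recorded as the mean over
#' outcomes of the Pearson correlation between observed and predicted test
#' values. A null twin repeats the identical procedure with the rows of `Y`
#' jointly permuted (a fresh permutation per iteration), preserving the
#' outcome inter-correlations under the null. Effect sizes compare the true
#' and null performance distributions.
#'
#' @param X n x m predictors (already restricted by `mask` if given).
#' @param Y n x p outcomes.
#' @param mask optional logical vector over columns of `X` (an edge mask).
#' @param n_iter number of resampling iterations (5000 in the full design;
#'   reduce for scaled-down runs).
#' @param train_frac training fraction of each split.
#' @param inner_k inner cross-validation folds for component selection.
#' @param ncomp_max largest candidate component count.
#' @param seed integer seed; the full procedure is deterministic given it.
#' @param mask_name label stored in the result.
#' @return object of class `resample_result`: `true_perf`, `null_perf`
#'   (length `n_iter`), `ks_stat`, `ks_p`, `cohens_d`, `median_true`,
#'   `pi_low`, `pi_high`, `n_iter`, `seed`, `mask_name`.
#' @export
resample_evaluate <- function(X, Y, mask = NULL, n_iter = 5000L,
                              train_frac = 0.8, inner_k = 5L, ncomp_max = 5L,
                              seed = 1L, mask_name = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  check_that(n >= 10, "need n >= 10 (got %d)", n)
  if (!is.null(mask)) {
    check_that(length(mask) == ncol(X), "mask length does not match ncol(X)")
    check_that(any(mask), "mask is empty")
    X <- X[, mask, drop = FALSE]
  }
  n_train <- round(train_frac * n)
  check_that(n_train >= inner_k && n_train < n,
             "train fraction leaves too few observations")
  run_once <- function(Yuse, idx) {
    a <- inner_cv_ncomp(X[idx, , drop = FALSE], Yuse[idx, , drop = FALSE],
                        k = inner_k, ncomp_max = ncomp_max)
    fit <- fit_plsr(X[idx, , drop = FALSE], Yuse[idx, , drop = FALSE], a)
    yh <- predict(fit, X[-idx, , drop = FALSE])
    mean_outcome_r(Yuse[-idx, , drop = FALSE], yh)
  }
  perf <- with_rng(seed, {
    true_perf <- numeric(n_iter); null_perf <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      idx <- sample(n, n_train)
      true_perf[it] <- run_once(Y, idx)
      Yp <- Y[sample(n), , drop = FALSE]
      null_perf[it] <- run_once(Yp, idx)
    }
    list(true = true_perf, null = null_perf)
  })
  es <- effect_size(perf$true, perf$null)
  sm <- summarize_performance(perf$true)
  structure(list(
    true_perf = perf$true, null_perf = perf$null,
    ks_stat = es$ks_stat, ks_p = es$ks_p, cohens_d = es$cohens_d,
    median_true = sm$median, pi_low = sm$pi_low, pi_high = sm$pi_high,
    n_iter = n_iter, seed = seed,
    mask_name = if (is.null(mask_name)) NA_character_ else mask_name
  ), class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("Resampled PLSR performance%s (%d iterations)\n",
              if (is.na(x$mask_name)) "" else paste0(" [", x$mask_name, "]"),
              x$n_iter))
  cat(sprintf("  median r = %.3f, 95%% PI [%.3f, %.3f]\n",
              x$median_true, x$pi_low, x$pi_high))
  cat(sprintf("  vs null: KS = %.3f (p = %.2g), Cohen's d = %.2f\n",
              x$ks_stat, x$ks_p, x$cohens_d))
  invisible(x)
}

#' Effect sizes between true and null performance distributions
#'
#' Two-sample Kolmogorov-Smirnov statistic with asymptotic p-value, and
#' Cohen's d with the pooled standard deviation.
#'
#' @param true_perf,null_perf numeric samples (each of size >= 2).
#' @return list with `ks_stat`, `ks_p`, `cohens_d`.
#' @export
effect_size <- function(true_perf, null_perf) {
  check_that(length(true_perf) >= 2 && length(null_perf) >= 2,
             "need at least 2 values per sample")
  ks <- suppressWarnings(stats::ks.test(true_perf, null_perf, exact = FALSE))
  n1 <- length(true_perf); n2 <- length(null_perf)
  pooled <- sqrt(((n1 - 1) * stats::var(true_perf) +
                    (n2 - 1) * stats::var(null_perf)) / (n1 + n2 - 2))
  check_that(pooled > 0, "pooled standard deviation is zero")
  list(ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       cohens_d = (mean(true_perf) - mean(null_perf)) / pooled)
}

#' Median and 95% prediction interval of a performance distribution
#'
#' Empirical median and 2.5/97.5 percentiles using the linear-interpolation
#' quantile rule (type 7).
#'
#' @param true_perf numeric sample of size >= 40.
#' @return list with `median`, `pi_low`, `pi_high`.
#' @export
summarize_performance <- function(true_perf) {
  check_that(length(true_perf) >= 40,
             "need at least 40 values for a stable 95%% interval (got %d)",
             length(true_perf))
  qs <- stats::quantile(true_perf, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  list(median = qs[2], pi_low = qs[1], pi_high = qs[3])
}
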