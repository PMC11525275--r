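#' Fit a multivariate partial least squares regression (SIMPLS)
#'
#' De Jong's SIMPLS on column-centered `X` and `Y` (no variance scaling,
#' matching the reference `plsregress` convention). Components maximize the
#' covariance between predictor and outcome scores via the singular-value
#' decomposition of the (deflated) cross-product matrix. Coefficients are
#' nested: the coefficient matrix for `a` components is
#' `R[, 1:a] %*% t(Q[, 1:a])`.
#'
#' @param X n x m predictor matrix (e.g. vectorized connectomes).
#' @param Y n x p outcome matrix (e.g. age, fluid cognition, log global WMH).
#' @param ncomp number of components A (<= min(n - 1, m)).
#' @return object of class `wmh_plsr`: `coefficients` (m x p, for `ncomp`
#'   components), `intercept` (length p), `x_means`, `y_means`, `weights`
#'   (m x A projection weights R), `x_loadings` (m x A), `y_loadings`
#'   (p x A), `scores` (n x A), `ncomp`.
#' @examples
#' X <- matrix(rnorm(100), 20, 5)
#' Y <- X %*% matrix(rnorm(10), 5, 2) + rnorm(20, sd = 0.1)
#' fit <- fit_plsr(X, Y, ncomp = 3)
#' head(predict(fit, X))
#' @export
fit_plsr <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  check_that(!anyNA(X) && !anyNA(Y), "missing values are not allowed")
  n <- nrow(X); m <- ncol(X); p <- ncol(Y)
  check_that(nrow(Y) == n, "X and Y disagree on n")
  amax <- min(n - 1L, m)
  check_that(ncomp >= 1 && ncomp <= amax,
             "ncomp = %d exceeds the achievable maximum %d", ncomp, amax)
  x_means <- colMeans(X); y_means <- colMeans(Y)
  Xc <- sweep(X, 2, x_means); Yc <- sweep(Y, 2, y_means)
  S <- crossprod(Xc, Yc)                      # m x p
  R <- matrix(0, m, ncomp)                    # projection weights
  P <- matrix(0, m, ncomp)                    # X loadings
  Q <- matrix(0, p, ncomp)                    # Y loadings
  Tt <- matrix(0, n, ncomp)                   # X scores
  V <- matrix(0, m, ncomp)                    # orthonormal basis of P
  for (a in seq_len(ncomp)) {
    sv <- svd(S, nu = 1, nv = 0)
    if (sv$d[1] < 1e-12) {
      stop(sprintf("rank exhausted at component %d; achievable maximum is %d",
                   a, a - 1L), call. = FALSE)
    }
    r <- sv$u[, 1]
    t_a <- Xc %*% r
    normt <- sqrt(sum(t_a^2))
    t_a <- t_a / normt
    r <- r / normt
    p_a <- crossprod(Xc, t_a)
    q_a <- crossprod(Yc, t_a)
    v <- p_a
    if (a > 1) {
      v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], p_a)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; P[, a] <- p_a; Q[, a] <- q_a; Tt[, a] <- t_a; V[, a] <- v
  }
  B <- R %*% t(Q)
  intercept <- as.numeric(y_means - crossprod(B, x_means))
  structure(list(
    coefficients = B, intercept = intercept,
    x_means = x_means, y_means = y_means,
    weights = R, x_loadings = P, y_loadings = Q, scores = Tt,
    ncomp = ncomp, outcome_names = colnames(Y)
  ), class = "wmh_plsr")
}

#' @export
coef.wmh_plsr <- function(object, ncomp = object$ncomp, ...) {
  check_that(ncomp >= 1 && ncomp <= object$ncomp,
             "ncomp must lie in 1..%d", object$ncomp)
  object$weights[, 1:ncomp, drop = FALSE] %*%
    t(object$y_loadings[, 1:ncomp, drop = FALSE])
}

#' @export
predict.wmh_plsr <- function(object, newdata, ncomp = object$ncomp, ...) {
  B <- coef(object, ncomp)
  intercept <- as.numeric(object$y_means - crossprod(B, object$x_means))
  out <- sweep(as.matrix(newdata) %*% B, 2, -intercept)
  colnames(out) <- object$outcome_names
  out
}

#' @export
print.wmh_plsr <- function(x, ...) {
  cat(sprintf("Partial least squares regression (SIMPLS): %d component(s), %d predictors, %d outcome(s)\n",
              x$ncomp, nrow(x$coefficients), ncol(x$coefficients)))
  invisible(x)
}

#' Squared correlation between observed and predicted outcomes
#'
#' @param Y,Y_hat matrices of matching shape.
#' @return numeric vector of per-column squared Pearson correlations.
#' @export
per_outcome_r2 <- function(Y, Y_hat) {
  Y <- as.matrix(Y); Y_hat <- as.matrix(Y_hat)
  check_that(all(dim(Y) == dim(Y_hat)), "Y and Y_hat shapes differ")
  vapply(seq_len(ncol(Y)), function(j) {
    check_that(stats::sd(Y[, j]) > 0 && stats::sd(Y_hat[, j]) > 0,
               "constant column %d", j)
    stats::cor(Y[, j], Y_hat[, j])^2
  }, numeric(1))
}

#' Cross-validated component selection for PLSR
#'
#' Seeded k-fold cross-validation: folds are a random near-equal partition
#' (no stratification); per fold a SIMPLS model with `ncomp_max` components
#' is fitted on the training portion and held-out predictions are assembled
#' for every candidate component count A = 1..`ncomp_max`. CV-MSEP is the
#' squared prediction error summed over outcomes and averaged over held-out
#' observations; CV-PCTVAR is `100 * (1 - CV_MSEP / baseline_MSE)` where the
#' baseline MSE is the sum of the (raw) outcome sample variances. The chosen
#' A minimizes CV-MSEP, ties going to the smaller A.
#'
#' @param X n x m predictors; `Y` n x p outcomes.
#' @param k number of folds (default 5).
#' @param ncomp_max largest candidate component count.
#' @param seed integer seed for the fold assignment.
#' @param keep_models keep the per-fold `wmh_plsr` fits (needed for
#'   [feature_importance()]).
#' @param standardize_y scale outcome columns to unit variance before
#'   fitting. The raw-outcome convention (default) matches the baseline-MSE
#'   bookkeeping; the standardized convention makes coefficient magnitudes
#'   comparable across outcomes and is used for feature importance.
#' @return object of class `plsr_cv`: `table` (per-A `msep`, `pctvar`),
#'   `baseline_mse`, `ncomp_best`, `r2_per_outcome` (held-out, at
#'   `ncomp_best`), `folds`, `fold_models`, `predictions` (assembled
#'   held-out predictions at `ncomp_best`), `seed`.
#' @export
select_components_cv <- function(X, Y, k = 5L, ncomp_max = 10L, seed = 1L,
                                 keep_models = TRUE, standardize_y = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (standardize_y) Y <- scale(Y)[, , drop = FALSE]
  n <- nrow(X)
  check_that(n >= 2 * k, "need n >= 2k observations (n = %d, k = %d)", n, k)
  ncomp_max <- min(ncomp_max, min(ncol(X), n - ceiling(n / k) - 1L))
  folds <- with_rng(seed, sample(rep(seq_len(k), length.out = n)))
  press <- matrix(0, ncomp_max, ncol(Y))   # summed sq error per A, outcome
  pred_best <- array(NA_real_, c(n, ncol(Y), ncomp_max))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_plsr(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], ncomp_max)
    if (keep_models) models[[f]] <- fit
    for (a in seq_len(ncomp_max)) {
      yh <- predict(fit, X[!tr, , drop = FALSE], ncomp = a)
      press[a, ] <- press[a, ] + colSums((Y[!tr, , drop = FALSE] - yh)^2)
      pred_best[!tr, , a] <- yh
    }
  }
  msep <- rowSums(press) / n
  baseline <- sum(apply(Y, 2, stats::var))
  pctvar <- 100 * (1 - msep / baseline)
  best <- which.min(msep)
  r2 <- per_outcome_r2(Y, pred_best[, , best])
  structure(list(
    table = data.frame(ncomp = seq_len(ncomp_max), msep = msep, pctvar = pctvar),
    baseline_mse = baseline,
    ncomp_best = best,
    r2_per_outcome = stats::setNames(r2, colnames(Y)),
    folds = folds,
    fold_models = if (keep_models) models else NULL,
    predictions = pred_best[, , best],
    seed = seed
  ), class = "plsr_cv")
}

#' @export
print.plsr_cv <- function(x, ...) {
  cat(sprintf("PLSR cross-validation (%d folds): best A = %d, CV-MSEP = %.4g, CV-PCTVAR = %.2f%% (baseline MSE %.4g)\n",
              max(x$folds), x$ncomp_best, x$table$msep[x$ncomp_best],
              x$table$pctvar[x$ncomp_best], x$baseline_mse))
  cat("held-out r^2 per outcome:\n")
  print(round(x$r2_per_outcome, 3))
  invisible(x)
}

#' Edge and ROI feature importance from cross-validated PLSR models
#'
#' Edge importance is the mean over folds of the absolute coefficient,
#' averaged across outcome columns; ROI importance sums the importances of
#' all edges incident to the region. Tables are sorted descending, with
#' ranks attached.
#'
#' @param models list of `wmh_plsr` fits sharing the same edge ordering
#'   (e.g. `fold_models` from [select_components_cv()]).
#' @param edge_map edge ordering from [edge_map()].
#' @param ncomp component count at which coefficients are taken (default:
#'   each model's fitted maximum).
#' @param per_outcome also return per-outcome edge importances.
#' @return object of class `plsr_importance`: `edges` (data frame `i`, `j`,
#'   `importance`, `rank`), `rois` (data frame `node_id`, `importance`,
#'   `rank`), and optionally `per_outcome` (m x p matrix).
#' @export
feature_importance <- function(models, edge_map, ncomp = NULL,
                               per_outcome = FALSE) {
  check_that(length(models) >= 1, "empty model list")
  m <- nrow(edge_map)
  acc <- NULL
  for (mod in models) {
    stopifnot(inherits(mod, "wmh_plsr"))
    B <- abs(coef(mod, if (is.null(ncomp)) mod$ncomp else ncomp))
    check_that(nrow(B) == m, "model coefficient rows (%d) do not match edge_map (%d)",
               nrow(B), m)
    acc <- if (is.null(acc)) B else acc + B
  }
  acc <- acc / length(models)
  imp <- rowMeans(acc)
  nodes <- sort(unique(c(edge_map$i, edge_map$j)))
  roi <- vapply(nodes, function(v) {
    sum(imp[edge_map$i == v | edge_map$j == v])
  }, numeric(1))
  edges <- data.frame(i = edge_map$i, j = edge_map$j, importance = imp)
  edges$rank <- rank(-edges$importance, ties.method = "first")
  rois <- data.frame(node_id = nodes, importance = roi)
  rois$rank <- rank(-rois$importance, ties.method = "first")
  structure(list(
    edges = edges[order(edges$rank), ],
    rois = rois[order(rois$rank), ],
    per_outcome = if (per_outcome) acc else NULL
  ), class = "plsr_importance")
}

#' @export
print.plsr_importance <- function(x, ...) {
  cat(sprintf("PLSR feature importance: %d edges, %d ROIs\n",
              nrow(x$edges), nrow(x$rois)))
  cat("top ROIs:\n")
  print(utils::head(x$rois, 5))
  invisible(x)
}
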