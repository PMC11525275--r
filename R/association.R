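#' Log-transform WMH volumes
#'
#' WMH volumes grow non-linearly with age, so all analyses work on the
#' natural log of the volume. Non-positive volumes are an error: either use
#' the generator's positivity guarantee or pass an explicit `offset`.
#'
#' @param volumes numeric vector of volumes (mm^3).
#' @param offset optional non-negative constant added before the log.
#' @return natural log of `volumes + offset`.
#' @export
log_wmh <- function(volumes, offset = 0) {
  check_that(is.numeric(volumes) && !anyNA(volumes),
             "volumes must be numeric without missing values")
  v <- volumes + offset
  if (any(v <= 0)) {
    stop(sprintf(paste0("%d volume(s) are <= 0 after offset %.3g; the log is undefined. ",
                        "Use strictly positive volumes or set `offset`."),
                 sum(v <= 0), offset), call. = FALSE)
  }
  log(v)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 4, both non-constant).
#' @return list with `r`, `p` (two-sided, t distribution on n - 2 df), `n`.
#' @export
pearson <- function(x, y) {
  check_that(length(x) == length(y), "x and y differ in length")
  n <- length(x)
  check_that(n >= 4, "need n >= 4 (got %d)", n)
  check_that(stats::sd(x) > 0 && stats::sd(y) > 0, "constant input")
  r <- stats::cor(x, y)
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  list(r = r, p = p, n = n)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on an intercept
#' plus the covariates, with the p-value from a t distribution on
#' `n - 2 - c` degrees of freedom (Fisher convention). With no covariates
#' this reduces exactly to [pearson()].
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data frame of c covariate columns, or `NULL`.
#' @return list with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    out <- pearson(x, y)
    out$df <- out$n - 2L
    return(out)
  }
  cv <- as.matrix(covariates)
  n <- length(x)
  check_that(n > ncol(cv) + 3, "need n > c + 3 (n = %d, c = %d)", n, ncol(cv))
  rx <- residualize(matrix(x, ncol = 1), cv)[, 1]
  ry <- residualize(matrix(y, ncol = 1), cv)[, 1]
  check_that(stats::sd(rx) > 1e-12 && stats::sd(ry) > 1e-12,
             "constant input: a variable is fully explained by the covariates")
  r <- stats::cor(rx, ry)
  df <- n - 2L - ncol(cv)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  list(r = r, p = p, n = n, df = df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values, capped at 1.
#' @export
bh_fdr <- function(pvalues) {
  check_that(is.numeric(pvalues) && !anyNA(pvalues),
             "p-values must be numeric without missing values")
  check_that(all(pvalues >= 0 & pvalues <= 1),
             "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' A-priori power for a Pearson correlation
#'
#' Power via the Fisher z approximation: with non-centrality
#' `lambda = atanh(r) * sqrt(n - 3)` and critical value `z_c`,
#' two-sided power is `Phi(lambda - z_c) + Phi(-lambda - z_c)`.
#'
#' @param r population correlation (|r| < 1).
#' @param n sample size (> 3).
#' @param alpha significance level.
#' @param two_sided logical; one-sided tests use the critical value
#'   `qnorm(1 - alpha)` in the direction of `r`.
#' @return power probability.
#' @examples
#' power_pearson(0.35, 68)  # ~0.84
#' @export
power_pearson <- function(r, n, alpha = 0.05, two_sided = TRUE) {
  check_that(abs(r) < 1, "|r| must be < 1")
  check_that(n > 3, "need n > 3")
  check_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  lambda <- atanh(r) * sqrt(n - 3)
  if (two_sided) {
    zc <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(lambda - zc) + stats::pnorm(-lambda - zc)
  } else {
    zc <- stats::qnorm(1 - alpha)
    stats::pnorm(abs(lambda) - zc)
  }
}

#' Correlation table with per-family FDR control
#'
#' Computes a row per requested pair: zero-order (or partial) correlation,
#' two-sided p, and Benjamini-Hochberg adjusted p within each declared
#' family. Families are explicit -- one per analysis table -- and never
#' pooled silently.
#'
#' @param data data frame holding all named columns.
#' @param pairs data frame with columns `x`, `y`, optional `covariates`
#'   (comma-separated column names, `""`/`NA` for none) and `family`
#'   (defaults to a single family).
#' @return data frame of class `correlation_table` with columns `x`, `y`,
#'   `n`, `r`, `p`, `p_fdr`, `family`.
#' @export
correlation_table <- function(data, pairs) {
  check_that(all(c("x", "y") %in% names(pairs)), "pairs needs columns x and y")
  if (is.null(pairs$family)) pairs$family <- "all"
  if (is.null(pairs$covariates)) pairs$covariates <- ""
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    xs <- data[[pairs$x[i]]]
    ys <- data[[pairs$y[i]]]
    check_that(!is.null(xs), "column '%s' not found", pairs$x[i])
    check_that(!is.null(ys), "column '%s' not found", pairs$y[i])
    cvn <- pairs$covariates[i]
    cv <- if (is.na(cvn) || !nzchar(cvn)) NULL else {
      nms <- trimws(strsplit(cvn, ",")[[1]])
      check_that(all(nms %in% names(data)), "covariate column(s) not found: %s",
                 paste(setdiff(nms, names(data)), collapse = ", "))
      as.matrix(data[, nms, drop = FALSE])
    }
    pc <- partial_correlation(xs, ys, cv)
    data.frame(x = pairs$x[i], y = pairs$y[i], n = pc$n, r = pc$r, p = pc$p,
               family = pairs$family[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$p_fdr[sel] <- bh_fdr(out$p[sel])
  }
  out <- out[, c("x", "y", "n", "r", "p", "p_fdr", "family")]
  class(out) <- c("correlation_table", "data.frame")
  out
}
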