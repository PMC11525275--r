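# fast OLS coefficient extraction
ols_coef <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  fit$coefficients
}

#' Simple and parallel-mediator models with bootstrap confidence intervals
#'
#' OLS path estimation: each mediator is regressed on \[1, x\] (a paths);
#' the outcome on \[1, x, mediators\] (b paths and direct effect c'); the
#' total effect c comes from the outcome on \[1, x\]. The indirect effect of
#' mediator i is `a_i * b_i`. Uncertainty comes from case resampling with
#' replacement: percentile 2.5/97.5 confidence intervals, bootstrap SE,
#' `z = point / SE`, and a two-sided normal p. Coefficients are
#' unstandardized (the predictor stays in native units). Significance is
#' keyed to the CI excluding zero.
#'
#' For the simple (single-mediator) model the OLS identity
#' `c = c' + a*b` holds exactly.
#'
#' @param x numeric predictor (e.g. age in years).
#' @param mediators numeric vector, matrix, or data frame of 1..K mediator
#'   columns (e.g. log WMH volumes).
#' @param y numeric outcome (e.g. fluid cognition).
#' @param n_boot bootstrap resamples (10000 in the full design).
#' @param seed integer seed.
#' @param level confidence level.
#' @return object of class `wmh_mediation`: `direct` (c' with SE/z/p/CI),
#'   `indirect` (data frame, one row per mediator), `total` (c), `n`,
#'   `n_boot`, `seed`.
#' @examples
#' ph <- simulate_phenotypes(sim_config(), seed = 3)
#' ff <- fluid_cognition(ph)
#' fit <- mediate(ph$age_years, log_wmh(ph$wmh_global_k07), ff$general,
#'                n_boot = 500, seed = 1)
#' fit
#' @export
mediate <- function(x, mediators, y, n_boot = 10000L, seed = 1L, level = 0.95) {
  M <- as.matrix(mediators)
  if (is.null(colnames(M))) colnames(M) <- paste0("m", seq_len(ncol(M)))
  K <- ncol(M)
  n <- length(x)
  check_that(length(y) == n && nrow(M) == n, "x, mediators, y disagree on n")
  check_that(n > K + 3, "need n > K + 3 (n = %d, K = %d)", n, K)
  check_that(!anyNA(x) && !anyNA(M) && !anyNA(y), "missing values are not allowed")
  check_that(stats::sd(x) > 0 && stats::sd(y) > 0 && all(apply(M, 2, stats::sd) > 0),
             "constant column")
  if (K > 1) {
    cn <- kappa(cbind(1, x, M), exact = TRUE)
    check_that(cn < 1e10, "mediators are collinear (condition number %.3g)", cn)
  }
  paths <- function(xv, Mv, yv) {
    Xa <- cbind(1, xv)
    a <- vapply(seq_len(K), function(i) ols_coef(Xa, Mv[, i])[2], numeric(1))
    cf <- ols_coef(cbind(1, xv, Mv), yv)
    b <- cf[3:(2 + K)]
    list(a = a, b = b, cprime = cf[2], indirect = a * b)
  }
  pt <- paths(x, M, y)
  total <- ols_coef(cbind(1, x), y)[2]
  boot <- with_rng(seed, {
    ind <- matrix(NA_real_, n_boot, K)
    cprime <- numeric(n_boot)
    for (bidx in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      pb <- paths(x[idx], M[idx, , drop = FALSE], y[idx])
      ind[bidx, ] <- pb$indirect
      cprime[bidx] <- pb$cprime
    }
    list(ind = ind, cprime = cprime)
  })
  alpha <- (1 - level) / 2
  qs <- apply(boot$ind, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              type = 7, names = FALSE)
  se <- apply(boot$ind, 2, stats::sd)
  z <- pt$indirect / se
  indirect <- data.frame(
    mediator = colnames(M),
    a = pt$a, b = pt$b,
    estimate = pt$indirect, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    ci_low = qs[1, ], ci_high = qs[2, ],
    significant = qs[1, ] > 0 | qs[2, ] < 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
  dse <- stats::sd(boot$cprime)
  dq <- stats::quantile(boot$cprime, c(alpha, 1 - alpha), type = 7, names = FALSE)
  direct <- list(estimate = pt$cprime, se = dse, z = pt$cprime / dse,
                 p = 2 * stats::pnorm(-abs(pt$cprime / dse)),
                 ci_low = dq[1], ci_high = dq[2])
  structure(list(direct = direct, indirect = indirect, total = total,
                 n = n, n_boot = n_boot, seed = seed, level = level),
            class = "wmh_mediation")
}

#' @export
print.wmh_mediation <- function(x, ...) {
  cat(sprintf("Mediation model (n = %d, %d mediator(s), %d bootstrap resamples)\n",
              x$n, nrow(x$indirect), x$n_boot))
  cat(sprintf("  total effect c      = %8.4f\n", x$total))
  cat(sprintf("  direct effect c'    = %8.4f  [%.4f, %.4f]\n",
              x$direct$estimate, x$direct$ci_low, x$direct$ci_high))
  for (i in seq_len(nrow(x$indirect))) {
    r <- x$indirect[i, ]
    cat(sprintf("  indirect via %-14s = %8.4f  [%.4f, %.4f]%s\n",
                r$mediator, r$estimate, r$ci_low, r$ci_high,
                if (r$significant) " *" else ""))
  }
  invisible(x)
}

#' @export
summary.wmh_mediation <- function(object, ...) {
  out <- object$indirect
  attr(out, "direct") <- object$direct
  attr(out, "total") <- object$total
  out
}

#' Seeded case-resampling bootstrap confidence interval
#'
#' Percentile interval for an arbitrary statistic of the data under case
#' resampling with replacement. A resample on which the statistic fails is
#' redrawn; more than 1% failures is an error.
#'
#' @param statistic function of the resampled data returning one number.
#' @param data vector, matrix, or data frame; rows are resampled.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with `low`, `high`, `se`, `replicates`, `n_failed`.
#' @export
bootstrap_ci <- function(statistic, data, n_boot = 1000L, seed = 1L,
                         level = 0.95) {
  n <- NROW(data)
  check_that(n >= 10, "need at least 10 observations (got %d)", n)
  take <- if (is.null(dim(data))) {
    function(idx) data[idx]
  } else {
    function(idx) data[idx, , drop = FALSE]
  }
  reps <- with_rng(seed, {
    out <- numeric(n_boot)
    failed <- 0L
    for (i in seq_len(n_boot)) {
      repeat {
        val <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                        error = function(e) NULL)
        if (!is.null(val) && is.finite(val)) break
        failed <- failed + 1L
        if (failed > 0.01 * n_boot + 1) {
          stop(sprintf("statistic failed on more than 1%% of resamples (%d failures)",
                       failed), call. = FALSE)
        }
      }
      out[i] <- val
    }
    list(values = out, failed = failed)
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps$values, c(alpha, 1 - alpha), type = 7, names = FALSE)
  list(low = qs[1], high = qs[2], se = stats::sd(reps$values),
       replicates = reps$values, n_failed = reps$failed)
}
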