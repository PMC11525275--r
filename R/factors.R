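#' Residualize columns on covariates
#'
#' Replaces every column of `x` by its ordinary-least-squares residual on an
#' intercept plus the covariates, the mechanism used to control test scores
#' for vocabulary and sex before factoring. Residuals are exactly
#' uncorrelated with each covariate.
#'
#' @param x numeric matrix or data frame (n x m), no missing values.
#' @param covariates numeric matrix or data frame (n x c); `NULL` or zero
#'   columns mean plain mean-centering.
#' @return numeric matrix of residuals, same dimensions and column names as `x`.
#' @export
residualize <- function(x, covariates = NULL) {
  x <- as.matrix(x)
  check_that(!anyNA(x), "x contains missing values")
  n <- nrow(x)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(scale(x, center = TRUE, scale = FALSE)[, , drop = FALSE])
  }
  cv <- as.matrix(covariates)
  check_that(!anyNA(cv), "covariates contain missing values")
  check_that(n > ncol(cv) + 1, "need n > c + 1 observations")
  design <- cbind(`(Intercept)` = 1, cv)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    keep <- qr_d$pivot[seq_len(qr_d$rank)]
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
    stop(sprintf("covariates are rank deficient; collinear columns: %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  res <- qr.resid(qr_d, x)
  dimnames(res) <- dimnames(x)
  res
}

#' Principal-axis factor analysis (first unrotated factor)
#'
#' Iterated principal-axis factoring of the correlation matrix: starting
#' communalities are the squared multiple correlations; the reduced
#' correlation matrix (communalities on the diagonal) is eigen-decomposed,
#' the leading eigenvector scaled by the square root of its eigenvalue
#' becomes the loading vector, communalities are updated to the squared
#' loadings, and the cycle repeats until the largest communality change
#' falls below `tol`. Factor scores are computed by the regression
#' (Thurstone) method by default and standardized to mean 0, SD 1.
#'
#' The sign convention fixes the loading of the first column to be
#' non-negative (the whole factor is flipped if needed), so a battery
#' oriented higher-is-better yields a higher-is-better factor.
#'
#' @param scores n x p numeric matrix or data frame of test scores.
#' @param n_factors number of factors; only the first unrotated factor is
#'   supported.
#' @param max_iter,tol iteration control for the communality updates.
#' @param method factor-score estimator, `"regression"` (default) or
#'   `"bartlett"`.
#' @return object of class `paf_fit`: `loadings`, `communalities`,
#'   `scores` (standardized factor scores), `iterations`, `method`.
#' @examples
#' z <- matrix(rnorm(300), 100, 3) + rnorm(100)
#' fit <- principal_axis_factor(z)
#' fit$loadings
#' @export
principal_axis_factor <- function(scores, n_factors = 1L, max_iter = 100L,
                                  tol = 1e-6,
                                  method = c("regression", "bartlett")) {
  method <- match.arg(method)
  check_that(n_factors == 1L, "only the first unrotated factor is supported")
  x <- as.matrix(scores)
  p <- ncol(x)
  n <- nrow(x)
  check_that(n > p, "need more observations than tests (n = %d, p = %d)", n, p)
  sds <- apply(x, 2, stats::sd)
  check_that(all(sds > 0), "zero-variance column(s): %s",
             paste(colnames(x)[sds == 0], collapse = ", "))
  R <- stats::cor(x)
  # squared multiple correlations as starting communalities
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  h <- if (is.null(Rinv)) rep(0.5, p) else 1 - 1 / diag(Rinv)
  h <- pmin(pmax(h, 0), 1 - 1e-6)
  lambda <- NULL
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h
    e <- eigen(Rh, symmetric = TRUE)
    lambda <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
    h_new <- lambda^2
    if (any(h_new > 1)) {
      warning("Heywood case: communality > 1 clipped", call. = FALSE)
      h_new <- pmin(h_new, 1 - 1e-6)
      lambda <- sign(lambda) * sqrt(h_new)
    }
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) break
    if (it == max_iter) {
      stop(sprintf("principal-axis iteration did not converge in %d steps (last communality change %.2e)",
                   max_iter, delta), call. = FALSE)
    }
  }
  if (lambda[1] < 0) lambda <- -lambda
  Z <- scale(x)
  weights <- switch(method,
    regression = solve(R, lambda),
    bartlett = {
      psi <- pmax(1 - h, 1e-8)
      li <- lambda / psi
      li / sum(lambda * li)
    })
  fs <- as.numeric(Z %*% weights)
  fs <- (fs - mean(fs)) / stats::sd(fs)
  structure(list(
    loadings = stats::setNames(lambda, colnames(x)),
    communalities = stats::setNames(h, colnames(x)),
    scores = fs,
    iterations = it,
    method = method
  ), class = "paf_fit")
}

#' @export
print.paf_fit <- function(x, ...) {
  cat(sprintf("Principal-axis factor (1 factor, %d tests, %d iterations, %s scores)\n",
              length(x$loadings), x$iterations, x$method))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Domain factor scores
#'
#' First unrotated principal-axis factor per cognitive domain (perceptual
#' speed, executive function, memory), each computed on that domain's four
#' tests with the same algorithm as [principal_axis_factor()], standardized.
#'
#' @param scores n x 12 matrix/data frame of (residualized) test scores.
#' @param domain_map named character vector mapping each test column to one
#'   of three domain labels, four tests per domain.
#' @param ... passed to [principal_axis_factor()].
#' @return n x 3 matrix of standardized domain scores, columns named by domain.
#' @export
domain_scores <- function(scores, domain_map = DOMAIN_MAP, ...) {
  x <- as.matrix(scores)
  check_that(all(names(domain_map) %in% colnames(x)),
             "domain_map names missing from scores: %s",
             paste(setdiff(names(domain_map), colnames(x)), collapse = ", "))
  tab <- table(domain_map)
  check_that(length(tab) == 3 && all(tab == 4),
             "domain_map must assign 12 tests to 3 domains, 4 each (got %s)",
             paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  out <- sapply(unique(domain_map), function(d) {
    cols <- names(domain_map)[domain_map == d]
    principal_axis_factor(x[, cols, drop = FALSE], ...)$scores
  })
  colnames(out) <- unique(domain_map)
  out
}

#' General and domain fluid-cognition factor scores
#'
#' The full cognitive-scoring pipeline: test scores are residualized on the
#' covariates (vocabulary and sex by default), then the first unrotated
#' principal-axis factor over all 12 tests gives the general fluid-cognition
#' score, and per-domain factors give the three domain scores.
#'
#' @param phenotypes phenotype table containing the test and covariate columns.
#' @param tests character vector of test column names (default the package's
#'   12-test battery).
#' @param covariates character vector of covariate column names.
#' @param domain_map named character vector, see [domain_scores()].
#' @param method factor-score estimator, see [principal_axis_factor()].
#' @param ... further arguments (e.g. `max_iter`, `tol`) passed to
#'   [principal_axis_factor()].
#' @return object of class `fluid_factors`: `loadings`, `communalities`,
#'   `general` (n standardized scores), `domains` (n x 3 matrix), `tests`,
#'   `covariates`.
#' @examples
#' ph <- simulate_phenotypes(sim_config(), seed = 2)
#' ff <- fluid_cognition(ph)
#' cor(ff$general, ph$latent_g)
#' @export
fluid_cognition <- function(phenotypes, tests = TEST_COLUMNS,
                            covariates = c("vocabulary", "sex"),
                            domain_map = DOMAIN_MAP,
                            method = c("regression", "bartlett"), ...) {
  method <- match.arg(method)
  check_that(all(tests %in% names(phenotypes)),
             "missing test columns: %s",
             paste(setdiff(tests, names(phenotypes)), collapse = ", "))
  x <- as.matrix(phenotypes[, tests, drop = FALSE])
  cv <- if (length(covariates)) as.matrix(phenotypes[, covariates, drop = FALSE]) else NULL
  res <- residualize(x, cv)
  fit <- principal_axis_factor(res, method = method, ...)
  dm <- domain_map[tests]
  doms <- domain_scores(res, dm, method = method, ...)
  structure(list(
    loadings = fit$loadings,
    communalities = fit$communalities,
    general = fit$scores,
    domains = doms,
    tests = tests,
    covariates = covariates
  ), class = "fluid_factors")
}

#' @export
print.fluid_factors <- function(x, ...) {
  cat(sprintf("Fluid-cognition factor scores (%d tests, covariates: %s)\n",
              length(x$tests), paste(x$covariates, collapse = ", ")))
  cat("general-factor loadings:\n")
  print(round(x$loadings, 3))
  cat("domain-score correlations:\n")
  print(round(stats::cor(x$domains), 3))
  invisible(x)
}
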