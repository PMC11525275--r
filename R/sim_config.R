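#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the generative model. Defaults encode the study
#' conditions the generator emulates: a 68-participant adult-lifespan sample
#' in three age cohorts, a strong negative age-fluid-cognition correlation,
#' log-normal global WMH volume rising with age and falling with cognition,
#' three correlated cognitive domains, tract-level WMH mediator columns, and
#' connectome edge-level signal concentrated on subcortical edges.
#'
#' @param cohort_sizes integer vector, participants per age cohort.
#' @param cohort_age_means,cohort_age_sds numeric per-cohort age mean/SD (years).
#' @param cohort_age_ranges list of length-2 numeric truncation ranges (years).
#' @param rho_age_g target correlation between age and latent fluid cognition g.
#' @param rho_age_wmh target correlation between age and log global WMH.
#' @param rho_g_wmh target correlation between g and log global WMH.
#' @param wmh_log_mean,wmh_log_sd mean/SD of log global WMH volume (log mm^3),
#'   default threshold series (k = 0.7).
#' @param domain_pair_corrs named numeric: target correlations between the
#'   executive-function/perceptual-speed/memory domain factors
#'   (`ef_ps`, `ef_m`, `ps_m`).
#' @param tract_wmh_loading loading of each tract-level WMH latent on the
#'   global WMH latent (delta).
#' @param signal_edge_decay kappa, per-SD multiplicative decay of expected
#'   streamline count on signal edges as the WMH latent increases.
#' @param signal_cortical_frac fraction of SUB-DMN and SUB-FPN edges included
#'   in the planted signal mask (SUB-SUB edges are always all included).
#' @param base_density_target target mean post-threshold connectome density.
#' @param test_loading loading of each observed test score on its domain factor.
#' @param seed integer default seed for generation.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config()
#' solve_latent_loadings(cfg)
#' @export
sim_config <- function(cohort_sizes = c(28L, 20L, 20L),
                       cohort_age_means = c(28.04, 48.75, 69.15),
                       cohort_age_sds = c(5.27, 5.80, 4.61),
                       cohort_age_ranges = list(c(18, 39), c(40, 59), c(60, 78)),
                       rho_age_g = -0.859,
                       rho_age_wmh = 0.68,
                       rho_g_wmh = -0.68,
                       wmh_log_mean = 6.11,
                       wmh_log_sd = 1.40,
                       domain_pair_corrs = c(ef_ps = 0.846, ef_m = 0.604, ps_m = 0.557),
                       tract_wmh_loading = 0.8,
                       signal_edge_decay = 0.6,
                       signal_cortical_frac = 0.5,
                       base_density_target = 0.33,
                       test_loading = 0.9,
                       seed = 1L) {
  k <- length(cohort_sizes)
  check_that(length(cohort_age_means) == k && length(cohort_age_sds) == k &&
               length(cohort_age_ranges) == k,
             "cohort parameter vectors must all have length %d", k)
  check_that(all(cohort_sizes >= 2),
             "every cohort needs at least 2 participants (correlations undefined otherwise)")
  rhos <- c(rho_age_g = rho_age_g, rho_age_wmh = rho_age_wmh, rho_g_wmh = rho_g_wmh)
  check_that(all(abs(rhos) < 1) && all(abs(domain_pair_corrs) < 1),
             "all target correlations must lie strictly inside (-1, 1)")
  check_that(all(c("ef_ps", "ef_m", "ps_m") %in% names(domain_pair_corrs)),
             "domain_pair_corrs must be named ef_ps, ef_m, ps_m")
  check_that(tract_wmh_loading > -1 && tract_wmh_loading < 1,
             "tract_wmh_loading must lie in (-1, 1)")
  check_that(signal_edge_decay >= 0, "signal_edge_decay must be non-negative")
  check_that(signal_cortical_frac >= 0 && signal_cortical_frac <= 1,
             "signal_cortical_frac must lie in [0, 1]")
  check_that(base_density_target > 0 && base_density_target < 1,
             "base_density_target must lie in (0, 1)")
  check_that(abs(test_loading) < 1, "test_loading must lie in (-1, 1)")
  cfg <- structure(list(
    cohort_sizes = as.integer(cohort_sizes),
    cohort_age_means = cohort_age_means,
    cohort_age_sds = cohort_age_sds,
    cohort_age_ranges = cohort_age_ranges,
    rho_age_g = rho_age_g,
    rho_age_wmh = rho_age_wmh,
    rho_g_wmh = rho_g_wmh,
    wmh_log_mean = wmh_log_mean,
    wmh_log_sd = wmh_log_sd,
    domain_pair_corrs = domain_pair_corrs,
    tract_wmh_loading = tract_wmh_loading,
    signal_edge_decay = signal_edge_decay,
    signal_cortical_frac = signal_cortical_frac,
    base_density_target = base_density_target,
    test_loading = test_loading,
    seed = as.integer(seed)
  ), class = "sim_config")
  # positive definiteness of the implied latent covariance, checked up front
  solve_latent_loadings(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d in %d cohorts (%s)\n", sum(x$cohort_sizes),
              length(x$cohort_sizes), paste(x$cohort_sizes, collapse = ", ")))
  cat(sprintf("  targets: r(age,g) = %.3f, r(age,logWMH) = %.3f, r(g,logWMH) = %.3f\n",
              x$rho_age_g, x$rho_age_wmh, x$rho_g_wmh))
  cat(sprintf("  log WMH ~ N(%.2f, %.2f^2); edge decay kappa = %.2f; density target %.2f\n",
              x$wmh_log_mean, x$wmh_log_sd, x$signal_edge_decay, x$base_density_target))
  invisible(x)
}

#' Solve the latent loadings implied by the target correlation structure
#'
#' The generator's latent model is, with `z` the standardized age score and
#' independent standard-normal shocks `eps`, `e`:
#' \deqn{g = \rho_{ag} z + \sqrt{1-\rho_{ag}^2}\,\epsilon}
#' \deqn{w = \alpha z + \beta(-g) + \gamma e}
#' where `g` is latent fluid cognition and `w` the standardized log-WMH
#' latent. `alpha` and `beta` solve the 2x2 linear system that makes
#' `corr(z, w)` and `corr(g, w)` hit their targets exactly in the
#' infinite-sample limit, and `gamma` normalizes `var(w) = 1`. Domain-factor
#' loadings `a_d` on `g` come from the triad identities
#' `a_EF * a_PS = r_EF,PS` etc., so that pairwise domain-factor correlations
#' equal their targets.
#'
#' @param config a [sim_config()].
#' @return list with `alpha`, `beta`, `gamma`, and `domain` (named vector
#'   `EF`, `PS`, `M`).
#' @export
solve_latent_loadings <- function(config) {
  stopifnot(inherits(config, "sim_config") || is.list(config))
  r_ag <- config$rho_age_g
  r_aw <- config$rho_age_wmh
  r_gw <- config$rho_g_wmh
  # corr(z,w) = alpha - beta * r_ag = r_aw ; corr(g,w) = alpha * r_ag - beta = r_gw
  beta <- (r_ag * r_aw - r_gw) / (1 - r_ag^2)
  alpha <- r_aw + beta * r_ag
  var_struct <- alpha^2 + beta^2 - 2 * alpha * beta * r_ag
  gamma2 <- 1 - var_struct
  if (gamma2 <= 0) {
    stop(sprintf(paste0(
      "target triple (rho_age_g = %.3f, rho_age_wmh = %.3f, rho_g_wmh = %.3f) ",
      "implies a non-positive-definite latent covariance (residual WMH variance %.4f)"),
      r_ag, r_aw, r_gw, gamma2), call. = FALSE)
  }
  dp <- config$domain_pair_corrs
  prod_ok <- dp[["ef_ps"]] * dp[["ef_m"]] * dp[["ps_m"]]
  if (prod_ok <= 0) {
    stop(sprintf(paste0(
      "domain_pair_corrs triple (%.3f, %.3f, %.3f) has non-positive product; ",
      "triad loadings are undefined"), dp[["ef_ps"]], dp[["ef_m"]], dp[["ps_m"]]),
      call. = FALSE)
  }
  a_ef <- sqrt(dp[["ef_ps"]] * dp[["ef_m"]] / dp[["ps_m"]])
  a_ps <- dp[["ef_ps"]] / a_ef
  a_m <- dp[["ef_m"]] / a_ef
  a <- c(EF = a_ef, PS = a_ps, M = a_m)
  if (any(a >= 1) || any(a <= 0)) {
    stop(sprintf(paste0(
      "domain_pair_corrs triple (%.3f, %.3f, %.3f) implies loadings outside (0,1): %s"),
      dp[["ef_ps"]], dp[["ef_m"]], dp[["ps_m"]],
      paste(sprintf("%.3f", a), collapse = ", ")), call. = FALSE)
  }
  list(alpha = alpha, beta = beta, gamma = sqrt(gamma2), domain = a)
}
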