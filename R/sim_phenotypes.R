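# Auxiliary WMH series: each is generated as a latent correlated with the
# global k=0.7 latent at `rho`, then mapped to log-volume scale with its own
# mean/SD. Means/SDs are the cohort summary values the generator emulates;
# rho 0.99 for the near-duplicate series (alternative threshold,
# periventricular) and 0.64 for deep WMH.
WMH_SERIES <- list(
  wmh_global_k05 = list(mean = 6.82, sd = 1.03, rho = 0.99),
  wmh_pv_k07     = list(mean = 5.89, sd = 1.39, rho = 0.99),
  wmh_deep_k07   = list(mean = 3.52, sd = 2.30, rho = 0.64)
)

# Tract-level WMH log-volume scales (anterior thalamic radiations carry the
# largest load, followed by forceps major, uncinate, cingulate bundle 1).
TRACT_SCALES <- list(
  uncinate      = c(mean = 4.6, sd = 1.4),
  forceps_major = c(mean = 4.9, sd = 1.4),
  cing1         = c(mean = 4.2, sd = 1.4),
  atr           = c(mean = 5.5, sd = 1.4)
)

#' Test-battery column names, 4 tests per domain
#' @keywords internal
TEST_COLUMNS <- c(sprintf("test_ps_%d", 1:4),
                  sprintf("test_ef_%d", 1:4),
                  sprintf("test_mem_%d", 1:4))

#' Default mapping of the 12 test columns to the three cognitive domains
#' @keywords internal
DOMAIN_MAP <- stats::setNames(
  rep(c("PS", "EF", "M"), each = 4), TEST_COLUMNS)

# truncated normal via rejection; ranges are wide relative to the SD so
# acceptance is high
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulate a phenotype table
#'
#' Draws a synthetic cohort from the latent model of [solve_latent_loadings()]:
#' ages from per-cohort truncated normals; latent fluid cognition `g` tied to
#' standardized age; a standardized log-WMH latent `w` tied to both; three
#' domain factors loading on `g`; 12 test scores (4 per domain) with loading
#' `test_loading` on their domain factor; global WMH volume
#' `exp(wmh_log_mean + wmh_log_sd * w)` plus correlated auxiliary series
#' (alternative threshold, periventricular, deep); four tract-level WMH
#' volumes sharing the global latent at loading `tract_wmh_loading`; sex
#' Bernoulli(0.5); vocabulary independent of age. Test scores are emitted
#' already oriented so that higher = better performance.
#'
#' The generator-truth columns `latent_g` and `latent_wmh` are retained for
#' recovery tests and are simulation-only fields.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return a `data.frame` with one row per participant: `participant_id`,
#'   `age_years`, `cohort`, `sex`, `vocabulary`, the 12 `test_*` columns,
#'   `wmh_global_k07`, `wmh_global_k05`, `wmh_pv_k07`, `wmh_deep_k07`
#'   (volumes, mm^3), `tract_*` volumes, `latent_g`, `latent_wmh`.
#' @examples
#' ph <- simulate_phenotypes(sim_config(), seed = 7)
#' cor(ph$age_years, log(ph$wmh_global_k07))
#' @export
simulate_phenotypes <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  check_that(all(config$cohort_sizes >= 2),
             "every cohort needs at least 2 participants (correlations undefined)")
  load <- solve_latent_loadings(config)
  n <- sum(config$cohort_sizes)
  with_rng(seed, {
    age <- unlist(lapply(seq_along(config$cohort_sizes), function(k) {
      rtrunc_norm(config$cohort_sizes[k], config$cohort_age_means[k],
                  config$cohort_age_sds[k],
                  config$cohort_age_ranges[[k]][1], config$cohort_age_ranges[[k]][2])
    }))
    z_age <- as.numeric(scale(age))
    g <- config$rho_age_g * z_age + sqrt(1 - config$rho_age_g^2) * stats::rnorm(n)
    w <- load$alpha * z_age + load$beta * (-g) + load$gamma * stats::rnorm(n)

    domains <- sapply(c("PS", "EF", "M"), function(d) {
      a <- load$domain[[if (d == "M") "M" else d]]
      a * g + sqrt(1 - a^2) * stats::rnorm(n)
    })
    tl <- config$test_loading
    tests <- matrix(NA_real_, n, 12, dimnames = list(NULL, TEST_COLUMNS))
    for (j in seq_len(12)) {
      d <- DOMAIN_MAP[[TEST_COLUMNS[j]]]
      f <- domains[, if (d == "M") "M" else d]
      tests[, j] <- tl * f + sqrt(1 - tl^2) * stats::rnorm(n)
    }

    wmh <- list(wmh_global_k07 = exp(config$wmh_log_mean + config$wmh_log_sd * w))
    for (nm in names(WMH_SERIES)) {
      s <- WMH_SERIES[[nm]]
      ws <- s$rho * w + sqrt(1 - s$rho^2) * stats::rnorm(n)
      wmh[[nm]] <- exp(s$mean + s$sd * ws)
    }

    delta <- config$tract_wmh_loading
    tract <- lapply(TRACT_SCALES, function(sc) {
      t_lat <- delta * w + sqrt(1 - delta^2) * stats::rnorm(n)
      exp(sc[["mean"]] + sc[["sd"]] * t_lat)
    })

    out <- data.frame(
      participant_id = sprintf("sub-%03d", seq_len(n)),
      age_years = age,
      cohort = rep(seq_along(config$cohort_sizes), times = config$cohort_sizes),
      sex = stats::rbinom(n, 1, 0.5),
      vocabulary = stats::rnorm(n, 58.53, 4.53),
      stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(tests))
    out$wmh_global_k07 <- wmh$wmh_global_k07
    out$wmh_global_k05 <- wmh$wmh_global_k05
    out$wmh_pv_k07 <- wmh$wmh_pv_k07
    out$wmh_deep_k07 <- wmh$wmh_deep_k07
    for (nm in names(tract)) out[[paste0("tract_", nm)]] <- tract[[nm]]
    out$latent_g <- g
    out$latent_wmh <- w
    out
  })
}
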