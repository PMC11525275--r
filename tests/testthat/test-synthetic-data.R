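test_that("fixture atlas satisfies its structural invariants and is seeded", {
  atlas <- make_atlas(seed = 1)
  expect_equal(nrow(atlas), 246)
  expect_equal(sum(atlas$lobe == "Subcortical"), 36)
  expect_equal(sum(atlas$network == "SUB"), sum(atlas$lobe == "Subcortical"))
  expect_equal(sort(atlas$node_id), 0:245)
  expect_equal(unname(table(atlas$lobe)[c("Frontal", "Temporal", "Parietal",
                                          "Insular", "Limbic", "Occipital",
                                          "Subcortical")]),
               c(70, 40, 38, 12, 14, 36, 36), ignore_attr = TRUE)
  # cortical networks roughly even: 210 / 7 = 30 each
  expect_true(all(table(atlas$network[atlas$network != "SUB"]) == 30))
  expect_true(all(atlas$volume_mm3 > 0))
  expect_identical(atlas, make_atlas(seed = 1))
  expect_false(identical(atlas$network, make_atlas(seed = 2)$network))
  for (s in c(3, 17)) {
    a <- make_atlas(seed = s)
    expect_equal(sum(a$network == "SUB"), sum(a$lobe == "Subcortical"))
  }
})

test_that("latent loadings solve the target correlation system in closed form", {
  load <- solve_latent_loadings(sim_config())
  expect_equal(unname(load$domain[["EF"]]), sqrt(0.846 * 0.604 / 0.557),
               tolerance = 1e-12)
  # decoupled system: no age-cognition and no cognition-WMH correlation
  dec <- solve_latent_loadings(sim_config(rho_age_g = 0, rho_g_wmh = 0))
  expect_equal(dec$beta, 0, tolerance = 1e-12)
  expect_equal(dec$alpha, 0.68, tolerance = 1e-12)
  # gamma normalizes the latent variance to 1
  for (cfg in list(sim_config(), sim_config(rho_age_g = -0.5, rho_age_wmh = 0.3,
                                            rho_g_wmh = -0.4))) {
    l <- solve_latent_loadings(cfg)
    v <- l$alpha^2 + l$beta^2 - 2 * l$alpha * l$beta * cfg$rho_age_g + l$gamma^2
    expect_equal(v, 1, tolerance = 1e-12)
  }
})

test_that("infeasible correlation targets are rejected, never clipped", {
  expect_error(sim_config(rho_age_g = 0, rho_age_wmh = 0.9, rho_g_wmh = 0.9),
               "non-positive-definite")
  expect_error(sim_config(domain_pair_corrs = c(ef_ps = 0.95, ef_m = 0.9,
                                                ps_m = 0.2)),
               "loadings outside")
  expect_error(sim_config(rho_age_g = 1.2), "inside")
  expect_error(sim_config(cohort_sizes = c(1, 20, 20)), "at least 2")
})

test_that("large-sample correlations converge to the calibration targets", {
  check_cfg <- function(cfg, seed) {
    ph <- simulate_phenotypes(sim_config(
      cohort_sizes = c(100000L, 2L, 2L),
      rho_age_g = cfg$rho_age_g, rho_age_wmh = cfg$rho_age_wmh,
      rho_g_wmh = cfg$rho_g_wmh), seed = seed)
    ph <- ph[ph$cohort == 1, ]
    lw <- log(ph$wmh_global_k07)
    expect_lt(abs(cor(ph$age_years, ph$latent_g) - cfg$rho_age_g), 0.011)
    expect_lt(abs(cor(ph$age_years, lw) - cfg$rho_age_wmh), 0.011)
    expect_lt(abs(cor(ph$latent_g, lw) - cfg$rho_g_wmh), 0.011)
  }
  check_cfg(list(rho_age_g = -0.859, rho_age_wmh = 0.68, rho_g_wmh = -0.68), 11)
  check_cfg(list(rho_age_g = -0.5, rho_age_wmh = 0.4, rho_g_wmh = -0.3), 12)
  check_cfg(list(rho_age_g = 0.3, rho_age_wmh = -0.2, rho_g_wmh = 0.5), 13)
})

test_that("auxiliary WMH series match their scale and correlation structure", {
  ph <- simulate_phenotypes(sim_config(cohort_sizes = c(100000L, 2L, 2L)),
                            seed = 31)
  ph <- ph[ph$cohort == 1, ]
  lg <- log(ph$wmh_global_k07)
  expect_equal(mean(lg), 6.11, tolerance = 0.02)
  expect_equal(sd(lg), 1.40, tolerance = 0.02)
  expect_equal(cor(lg, log(ph$wmh_global_k05)), 0.99, tolerance = 0.01)
  expect_equal(cor(lg, log(ph$wmh_pv_k07)), 0.99, tolerance = 0.01)
  expect_equal(cor(lg, log(ph$wmh_deep_k07)), 0.64, tolerance = 0.015)
  expect_true(all(ph[paste0("tract_", c("uncinate", "forceps_major",
                                        "cing1", "atr"))] > 0))
  # tract series share the global latent at the configured loading
  expect_equal(cor(log(ph$tract_atr), ph$latent_wmh), 0.8, tolerance = 0.015)
  # vocabulary independent of age
  expect_lt(abs(cor(ph$age_years, ph$vocabulary)), 0.02)
})

test_that("the null configuration generates uncorrelated variables", {
  cfg0 <- sim_config(rho_age_g = 0, rho_age_wmh = 0, rho_g_wmh = 0)
  rs <- vapply(1:200, function(s) {
    p <- simulate_phenotypes(cfg0, seed = s)
    c(cor(p$age_years, p$latent_g),
      cor(p$age_years, log(p$wmh_global_k07)),
      cor(p$latent_g, log(p$wmh_global_k07)))
  }, numeric(3))
  expect_true(all(abs(rowMeans(rs)) < 0.03))
})

test_that("phenotype generation is deterministic and cohort-structured", {
  cfg <- sim_config()
  a <- simulate_phenotypes(cfg, seed = 5)
  b <- simulate_phenotypes(cfg, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$age_years, simulate_phenotypes(cfg, seed = 6)$age_years))
  expect_equal(nrow(a), 68)
  for (k in 1:3) {
    ages <- a$age_years[a$cohort == k]
    expect_true(all(ages >= cfg$cohort_age_ranges[[k]][1] &
                      ages <= cfg$cohort_age_ranges[[k]][2]))
    expect_length(ages, cfg$cohort_sizes[k])
  }
  expect_false(anyNA(a))
  expect_true(all(a$wmh_global_k07 > 0))
})

test_that("streamline thresholding zeroes sub-threshold counts only", {
  W <- matrix(c(0, 2, 3, 2, 0, 7, 3, 7, 0), 3)
  thr <- apply_streamline_threshold(W)
  expect_equal(thr, matrix(c(0, 0, 3, 0, 0, 7, 3, 7, 0), 3))
  expect_equal(apply_streamline_threshold(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_equal(max(abs(thr - t(thr))), 0)
  expect_error(apply_streamline_threshold(matrix(0, 2, 3)), "square")
})

test_that("simulated connectomes satisfy the stack invariants", {
  fx <- fixture_cohort()
  expect_s3_class(fx$cs, "connectome_set")
  expect_silent(validate_connectome_set(fx$cs))
  expect_equal(length(fx$cs$matrices), 68)
  expect_equal(nrow(fx$cs$edge_map), 30135)
  # determinism
  cs2 <- simulate_connectomes(fx$ph, fixture_atlas(), fx$cfg, seed = 22)
  expect_identical(fx$cs$matrices, cs2$matrices)
  expect_identical(fx$cs$signal_mask, cs2$signal_mask)
  # mean post-threshold density near the calibration target
  dens <- vapply(fx$cs$matrices, graph_density, numeric(1))
  expect_lt(abs(mean(dens) - 0.33), 0.05)
  expect_error(simulate_connectomes(fx$ph[0, ], fixture_atlas(), fx$cfg),
               "empty")
})

test_that("planted signal edges track the WMH latent and others do not", {
  fx <- fixture_cohort()
  X <- connectome_edges(fx$cs)
  b <- as.numeric(scale(fx$ph$latent_wmh))
  ok <- apply(X, 2, sd) > 0
  cors <- rep(NA_real_, ncol(X))
  cors[ok] <- as.numeric(cor(X[, ok], b))
  sig <- fx$cs$signal_mask
  expect_lt(mean(cors[sig & ok]), -0.2)
  expect_lt(abs(mean(cors[!sig & ok])), 0.05)
})

test_that("with zero edge decay no edge correlates with the latent beyond chance", {
  cfg0 <- sim_config(signal_edge_decay = 0)
  atlas <- fixture_atlas()
  crit <- qt(0.975, 68 - 2) / sqrt(68 - 2 + qt(0.975, 68 - 2)^2)
  frac <- vapply(1:3, function(s) {
    ph <- simulate_phenotypes(cfg0, seed = 40 + s)
    cs <- simulate_connectomes(ph, atlas, cfg0, seed = 50 + s)
    X <- connectome_edges(cs)
    b <- as.numeric(scale(ph$latent_wmh))
    ok <- apply(X, 2, sd) > 0
    cors <- as.numeric(cor(X[, ok], b))
    mean(abs(cors) > crit)
  }, numeric(1))
  expect_gt(mean(frac), 0.03)
  expect_lt(mean(frac), 0.07)
})
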