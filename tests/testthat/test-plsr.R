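test_that("the edge map is lexicographic and bijective with the upper triangle", {
  em <- edge_map(246)
  expect_equal(nrow(em), 30135)
  expect_true(all(em$i < em$j))
  # strictly lexicographic order
  key <- em$i * 246 + em$j
  expect_true(all(diff(key) > 0))
  em3 <- edge_map(3)
  expect_equal(em3$i, c(0, 0, 1))
  expect_equal(em3$j, c(1, 2, 2))
  W <- matrix(c(0, 5, 7, 5, 0, 11, 7, 11, 0), 3)
  expect_equal(vectorize(W), c(5, 7, 11))
  set.seed(20)
  A <- matrix(rnorm(100), 10); A <- A + t(A); diag(A) <- 0
  expect_equal(devectorize(vectorize(A), 10), A)
  expect_error(vectorize(matrix(c(0, 1, 2, 0), 2)), "asymmetric")
})

test_that("SIMPLS collapses to OLS in identifiable regimes", {
  set.seed(21)
  # univariate: one predictor, one component -> the OLS slope
  x <- matrix(rnorm(30)); y <- 2 * x + rnorm(30, sd = 0.3)
  fit <- fit_plsr(x, y, 1)
  expect_equal(as.numeric(fit$coefficients),
               as.numeric(coef(lm(y ~ x))[2]), tolerance = 1e-10)
  # full rank: A = m recovers the least-squares solution
  X <- matrix(rnorm(100), 20, 5)
  Y <- X %*% matrix(rnorm(10), 5, 2) + matrix(rnorm(40), 20, 2)
  fit5 <- fit_plsr(X, Y, 5)
  B_ols <- solve(crossprod(scale(X, scale = FALSE))) %*%
    crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE))
  expect_lt(max(abs(fit5$coefficients - B_ols)), 1e-8)
  # predicting the training mean row returns the outcome means
  expect_equal(as.numeric(predict(fit5, matrix(colMeans(X), 1))),
               colMeans(Y), tolerance = 1e-8, ignore_attr = TRUE)
  # duplicated outcome column -> identical coefficient columns
  fitd <- fit_plsr(X, cbind(Y[, 1], Y[, 1]), 3)
  expect_lt(max(abs(fitd$coefficients[, 1] - fitd$coefficients[, 2])), 1e-10)
})

test_that("SIMPLS exceeds neither the data rank nor the requested components", {
  set.seed(22)
  X <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(8), 2, 4)  # rank 2
  Y <- matrix(rnorm(20))
  expect_error(fit_plsr(X, Y, 4), "rank exhausted|achievable")
  expect_error(fit_plsr(matrix(rnorm(20), 10, 2), matrix(rnorm(10)), 5),
               "achievable maximum")
})

test_that("SIMPLS agrees with an independent NIPALS implementation", {
  # the two algorithms coincide for a univariate outcome (for multivariate
  # outcomes they provably differ beyond the first component; the
  # full-rank OLS oracle covers that case)
  set.seed(23)
  X <- scale(matrix(rnorm(200), 20, 10))
  y <- scale(X[, 1:3] %*% matrix(rnorm(3)) + rnorm(20))
  for (a in 1:3) {
    fit <- fit_plsr(X, y, a)
    oracle <- nipals_pls(X, y, a)
    expect_lt(max(abs(predict(fit, X) - oracle$predict(X))), 1e-6)
  }
})

test_that("predictions are invariant to predictor permutation", {
  set.seed(24)
  X <- matrix(rnorm(200), 20, 10)
  Y <- matrix(rnorm(40), 20, 2)
  fit <- fit_plsr(X, Y, 3)
  perm <- sample(10)
  fit_p <- fit_plsr(X[, perm], Y, 3)
  expect_lt(max(abs(predict(fit, X) - predict(fit_p, X[, perm]))), 1e-8)
  expect_lt(max(abs(fit$coefficients[perm, ] - fit_p$coefficients)), 1e-8)
})

test_that("cross-validation recovers an exact linear signal", {
  set.seed(25)
  # rank-3 predictors carrying an exact linear signal: three components
  # span the solution and the held-out error collapses to numerical zero
  X <- matrix(rnorm(150), 50, 3) %*% matrix(rnorm(24), 3, 8)
  Y <- X[, 1:3] %*% matrix(c(1, -2, 0.5, 2, 1, -1), 3, 2)
  cv <- select_components_cv(X, Y, k = 5, ncomp_max = 3, seed = 2)
  expect_lt(cv$table$msep[3], 1e-6 * cv$baseline_mse)
  # baseline MSE is the sum of the raw outcome variances
  expect_equal(cv$baseline_mse, sum(apply(Y, 2, var)), tolerance = 1e-10)
  # determinism: same seed, same folds and tables
  cv2 <- select_components_cv(X, Y, k = 5, ncomp_max = 3, seed = 2)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$table, cv2$table, tolerance = 1e-15)
  expect_error(select_components_cv(X[1:8, ], Y[1:8, ], k = 5), "n >= 2k")
})

test_that("held-out accuracy is near zero without predictor-outcome signal", {
  r2s <- vapply(1:50, function(s) {
    set.seed(300 + s)
    X <- matrix(rnorm(40 * 10), 40, 10)
    Y <- matrix(rnorm(40 * 2), 40, 2)
    cv <- select_components_cv(X, Y, k = 5, ncomp_max = 3, seed = s,
                               keep_models = FALSE)
    mean(cv$r2_per_outcome)
  }, numeric(1))
  expect_lt(mean(r2s), 0.1)
})

test_that("per-outcome r-squared is a squared correlation", {
  set.seed(26)
  Y <- matrix(rnorm(60), 30, 2)
  expect_equal(per_outcome_r2(Y, Y), c(1, 1))
  expect_equal(per_outcome_r2(Y, -Y), c(1, 1))
  yh <- Y + matrix(rnorm(60), 30, 2)
  expect_equal(per_outcome_r2(Y, yh),
               c(cor(Y[, 1], yh[, 1])^2, cor(Y[, 2], yh[, 2])^2),
               tolerance = 1e-12)
  expect_error(per_outcome_r2(Y, matrix(1, 30, 2)), "constant")
  expect_error(per_outcome_r2(Y, yh[1:10, ]), "shapes")
})

test_that("feature importance ranks planted coefficients and sums incidences", {
  em <- edge_map(5)          # 10 edges
  # synthetic single model: all weight on edge 4 = pair (0, 4)
  fake <- structure(list(
    weights = matrix(as.numeric(seq_len(nrow(em)) == 4)),
    y_loadings = matrix(1), ncomp = 1L,
    x_means = numeric(nrow(em)), y_means = 0, outcome_names = "y"
  ), class = "wmh_plsr")
  imp <- feature_importance(list(fake), em)
  top <- imp$edges[1, ]
  expect_equal(c(top$i, top$j), c(em$i[4], em$j[4]))
  expect_true(all(imp$rois$node_id[imp$rois$rank <= 2] %in% c(em$i[4], em$j[4])))
  # ROI importance equals the brute-force incidence sum
  set.seed(27)
  X <- matrix(rnorm(30 * nrow(em)), 30)
  Y <- matrix(rnorm(60), 30, 2)
  fit <- fit_plsr(X, Y, 2)
  imp2 <- feature_importance(list(fit), em)
  ev <- imp2$edges[order(imp2$edges$i, imp2$edges$j), "importance"]
  for (v in 0:4) {
    oracle <- sum(ev[em$i == v | em$j == v])
    expect_equal(imp2$rois$importance[imp2$rois$node_id == v], oracle,
                 tolerance = 1e-10)
  }
  expect_error(feature_importance(list(), em), "empty")
})

test_that("edge importance concentrates on the planted signal edges", {
  atlas <- fixture_atlas()
  cfg <- sim_config()
  wins <- vapply(1:3, function(s) {
    ph <- simulate_phenotypes(cfg, seed = 400 + s)
    cs <- simulate_connectomes(ph, atlas, cfg, seed = 500 + s)
    X <- connectome_edges(cs)
    Y <- cbind(ph$age_years, ph$latent_g, log(ph$wmh_global_k07))
    cv <- select_components_cv(X, Y, k = 5, ncomp_max = 3, seed = s,
                               standardize_y = TRUE)
    imp <- feature_importance(cv$fold_models, cs$edge_map, ncomp = cv$ncomp_best)
    ev <- imp$edges[order(imp$edges$i, imp$edges$j), "importance"]
    mean(ev[cs$signal_mask]) > mean(ev[!cs$signal_mask])
  }, logical(1))
  expect_true(all(wins))
})
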