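triangle <- function(w12 = 1, w13 = 1, w23 = 1) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- w12
  W[1, 3] <- W[3, 1] <- w13
  W[2, 3] <- W[3, 2] <- w23
  W
}

two_cliques <- function(k = 3) {
  W <- matrix(0, 2 * k, 2 * k)
  W[1:k, 1:k] <- 1
  W[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(W) <- 0
  W
}

test_that("density counts supported node pairs", {
  expect_equal(graph_density(triangle()), 1)
  expect_equal(graph_density(triangle(1, 1, 0)), 2 / 3)
  expect_equal(graph_density(matrix(0, 4, 4)), 0)
  expect_error(graph_density(-triangle()), "negative")
})

test_that("Onnela clustering matches hand-evaluated formulas", {
  expect_equal(clustering_onnela(triangle()), 1)
  # path graph: no closed triangles
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- 1; P[2, 3] <- P[3, 2] <- 1
  expect_equal(clustering_onnela(P), 0)
  # weighted triangle (1, 0.5, 0.5): every node sees the same triangle
  # intensity (1 * 0.5 * 0.5)^(1/3) on normalized weights
  W <- triangle(1, 0.5, 0.5)
  val <- (1 * 0.5 * 0.5)^(1 / 3)
  expect_equal(clustering_onnela(W), val, tolerance = 1e-12)
  expect_warning(z <- clustering_onnela(matrix(0, 3, 3)), "all-zero")
  expect_equal(z, 0)
})

test_that("modularity matches hand and exhaustive evaluations", {
  W <- two_cliques(3)
  # one module: Q = 0 at gamma 1
  expect_equal(modularity_q(W, rep(1, 6)), 0, tolerance = 1e-12)
  # two disjoint triangles at the component partition
  expect_equal(modularity_q(W, rep(1:2, each = 3)), 0.5, tolerance = 1e-12)
  # the true partition is the exhaustive maximum
  parts <- all_partitions(6)
  qs <- vapply(parts, function(p) modularity_q(W, p), numeric(1))
  expect_equal(max(qs), 0.5, tolerance = 1e-12)
  expect_true(same_partition(parts[[which.max(qs)]], rep(1:2, each = 3)))
  expect_error(modularity_q(matrix(0, 3, 3), rep(1, 3)), "empty")
})

test_that("modularity decomposes exactly over disconnected components", {
  set.seed(40)
  A <- matrix(runif(16), 4); A <- A + t(A); diag(A) <- 0
  B <- matrix(runif(25), 5); B <- B + t(B); diag(B) <- 0
  Wb <- matrix(0, 9, 9); Wb[1:4, 1:4] <- A; Wb[5:9, 5:9] <- B
  wA <- sum(A) / sum(Wb); wB <- sum(B) / sum(Wb)
  # each component collapsed to one module: Q = 1 - sum of squared weight shares
  expect_equal(modularity_q(Wb, c(rep(1, 4), rep(2, 5))),
               1 - wA^2 - wB^2, tolerance = 1e-12)
  # finer partitions: component contributions rescale as w_c E_c - w_c^2 D_c
  pA <- c(1, 1, 2, 2); pB <- c(1, 2, 2, 3, 3)
  q_direct <- modularity_q(Wb, c(pA, pB + 10))
  comp_terms <- function(M, p, w) {
    s <- rowSums(M); m2 <- sum(M)
    e <- vapply(unique(p), function(c) sum(M[p == c, p == c]) / m2, numeric(1))
    d <- vapply(unique(p), function(c) (sum(s[p == c]) / m2)^2, numeric(1))
    w * sum(e) - w^2 * sum(d)
  }
  expect_equal(q_direct, comp_terms(A, pA, wA) + comp_terms(B, pB, wB),
               tolerance = 1e-12)
  # pairwise-definition oracle on the full matrix
  s <- rowSums(Wb); m2 <- sum(Wb)
  memb <- c(pA, pB + 10)
  same <- outer(memb, memb, "==")
  q_pairwise <- sum((Wb - outer(s, s) / m2) * same) / m2
  expect_equal(q_direct, q_pairwise, tolerance = 1e-12)
})

test_that("Louvain never beats the exhaustive modularity maximum on small graphs", {
  set.seed(41)
  parts <- all_partitions(8)
  for (rep in 1:3) {
    W <- matrix(0, 8, 8)
    W[upper.tri(W)] <- rbinom(28, 1, 0.4) * runif(28, 0.5, 2)
    W <- W + t(W)
    if (sum(W) == 0) next
    qmax <- max(vapply(parts, function(p) modularity_q(W, p), numeric(1)))
    cp <- consensus_partition(W, gamma = 1, n_runs = 20, seed = rep)
    expect_lte(cp$q, qmax + 1e-12)
  }
})

test_that("consensus clustering is exact on disjoint cliques and deterministic", {
  W <- two_cliques(4)
  cp <- consensus_partition(W, gamma = 1, n_runs = 20, seed = 3)
  expect_true(same_partition(cp$membership, rep(1:2, each = 4)))
  expect_equal(cp$q, modularity_q(W, cp$membership), tolerance = 1e-12)
  cp2 <- consensus_partition(W, gamma = 1, n_runs = 20, seed = 3)
  expect_identical(cp, cp2)
})

test_that("consensus clustering recovers a planted four-block structure", {
  make_planted <- function(seed) {
    set.seed(seed)
    n <- 16; blocks <- rep(1:4, each = 4)
    P <- ifelse(outer(blocks, blocks, "=="), 0.95, 0.05)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- rbinom(n * (n - 1) / 2, 1, P[upper.tri(P)])
    W <- W + t(W)
    list(W = W, blocks = blocks)
  }
  hits <- vapply(1:5, function(s) {
    g <- make_planted(600 + s)
    cp <- consensus_partition(g$W, gamma = 1, n_runs = 30, seed = s)
    same_partition(cp$membership, g$blocks)
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("communicability matches closed forms and is scale invariant", {
  expect_equal(communicability_global(matrix(0, 4, 4)), 0)
  # 2-node unit graph: strength-normalized matrix is the anti-diagonal, and
  # exp of it has off-diagonal sinh(1)
  W2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(communicability_global(W2), sinh(1), tolerance = 1e-12)
  set.seed(42)
  A <- matrix(runif(36), 6); A <- A + t(A); diag(A) <- 0
  expect_equal(communicability_global(A), communicability_global(3.7 * A),
               tolerance = 1e-12)
  # isolated nodes are excluded, not poisoned
  Ai <- rbind(cbind(A, 0), 0)
  expect_equal(communicability_global(Ai), communicability_global(A),
               tolerance = 1e-12)
})

test_that("per-participant metric tables assemble all requested measures", {
  fx <- fixture_cohort()
  sub <- fx$cs
  sub$participant_ids <- sub$participant_ids[1:4]
  sub$matrices <- sub$matrices[1:4]
  gm <- graph_metrics(sub, fixture_atlas(), gammas = c(1, 1.5), n_runs = 10,
                      seed = 2)
  expect_equal(nrow(gm), 4)
  expect_named(gm, c("participant_id", "density", "clustering",
                     "modularity_apriori", "consensus_q_1", "consensus_q_1.5",
                     "communicability"))
  expect_true(all(gm$density > 0 & gm$density < 1))
  expect_true(all(is.finite(as.matrix(gm[, -1]))))
  # consensus Q at data-driven partitions is at least the a-priori Q
  expect_true(all(gm$consensus_q_1 >= gm$modularity_apriori - 1e-8))
})

test_that("metric regressions report consistent coefficients", {
  set.seed(43)
  fx <- fixture_cohort()
  ph <- fx$ph
  ph$fluid <- ph$latent_g
  lw <- log_wmh(ph$wmh_global_k07)
  metrics <- data.frame(participant_id = ph$participant_id,
                        exact = 0.5 + 2 * lw,
                        noise = rnorm(nrow(ph)))
  ma <- suppressWarnings(metrics_regressions(metrics, ph, fluid_col = "fluid"))
  ex_un <- ma$regressions[ma$regressions$metric == "exact" &
                            ma$regressions$model == "unadjusted", ]
  expect_equal(ex_un$b, 2, tolerance = 1e-10)
  expect_equal(ex_un$beta, 1, tolerance = 1e-10)
  expect_equal(ex_un$r_squared, 1, tolerance = 1e-10)
  # beta = b * SD(x) / SD(y) identity on the noise metric
  no_un <- ma$regressions[ma$regressions$metric == "noise" &
                            ma$regressions$model == "unadjusted", ]
  expect_equal(no_un$beta, no_un$b * sd(lw) / sd(metrics$noise),
               tolerance = 1e-10)
  expect_s3_class(ma$correlations, "correlation_table")
  expect_error(metrics_regressions(metrics[c(2:nrow(metrics), 1), ], ph),
               "misaligned")
})

test_that("regression intervals cover the null at their nominal rate", {
  set.seed(44)
  covered <- vapply(1:500, function(i) {
    lw <- rnorm(68)
    metric <- rnorm(68)   # independent of everything
    fit <- lm(metric ~ lw)
    ci <- confint(fit)["lw", ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})
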