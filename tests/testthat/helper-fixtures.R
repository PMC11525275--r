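# Shared fixtures (built once per test run) and independent oracles.

fix_env <- new.env()

fixture_atlas <- function() {
  if (is.null(fix_env$atlas)) fix_env$atlas <- make_atlas(seed = 1)
  fix_env$atlas
}

fixture_cohort <- function() {
  if (is.null(fix_env$ph)) {
    fix_env$cfg <- sim_config()
    fix_env$ph <- simulate_phenotypes(fix_env$cfg, seed = 21)
    fix_env$cs <- simulate_connectomes(fix_env$ph, fixture_atlas(),
                                       fix_env$cfg, seed = 22)
  }
  list(cfg = fix_env$cfg, ph = fix_env$ph, cs = fix_env$cs)
}

# draw n samples from a given 3x3 correlation matrix (Cholesky)
rmvn_corr <- function(n, R) {
  L <- chol(R)
  matrix(stats::rnorm(n * nrow(R)), n) %*% L
}

# --- independent oracles -------------------------------------------------

# NIPALS PLS2 (regression mode), centered data; independent of the SIMPLS
# implementation under test
nipals_pls <- function(X, Y, ncomp, max_iter = 500, tol = 1e-12) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  x_means <- attr(X, "scaled:center"); y_means <- attr(Y, "scaled:center")
  n <- nrow(X); m <- ncol(X); p <- ncol(Y)
  W <- matrix(0, m, ncomp); P <- matrix(0, m, ncomp)
  Q <- matrix(0, p, ncomp); Tt <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(apply(Y, 2, stats::var)), drop = FALSE]
    t_old <- rep(Inf, n)
    for (i in seq_len(max_iter)) {
      w <- crossprod(X, u); w <- w / sqrt(sum(w^2))
      t_new <- X %*% w
      q <- crossprod(Y, t_new); q <- q / sqrt(sum(q^2))
      u <- Y %*% q
      if (sum((t_new - t_old)^2) < tol * sum(t_new^2)) break
      t_old <- t_new
    }
    t_a <- as.numeric(t_new)
    p_a <- crossprod(X, t_a) / sum(t_a^2)
    q_a <- crossprod(Y, t_a) / sum(t_a^2)
    X <- X - tcrossprod(t_a, p_a)
    Y <- Y - tcrossprod(t_a, q_a)
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- q_a; Tt[, a] <- t_a
  }
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  list(B = B, intercept = y_means - as.numeric(crossprod(B, x_means)),
       predict = function(newX) {
         sweep(as.matrix(newX) %*% B, 2,
               -(y_means - as.numeric(crossprod(B, x_means))))
       })
}

# brute-force Benjamini-Hochberg: q_(i) = min over j >= i of p_(j) * m / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sort(p)[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# brute-force two-sample KS statistic: maximum ECDF gap over all data points
ks_brute <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# enumerate all set partitions of 1..n as membership vectors (restricted
# growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxblock) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (b in seq_len(maxblock + 1)) {
      rec(c(prefix, b), max(maxblock, b))
    }
  }
  rec(c(1L), 1L)
  out
}

# same partition up to relabeling?
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
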