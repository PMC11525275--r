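#' Global density of a weighted graph
#'
#' Fraction of node pairs with nonzero weight.
#'
#' @param W symmetric non-negative matrix with zero diagonal.
#' @return density in \[0, 1\].
#' @export
graph_density <- function(W) {
  check_that(is.matrix(W) && nrow(W) == ncol(W), "W must be square")
  check_that(all(W >= 0), "negative weights are not allowed")
  ut <- W[upper.tri(W)]
  mean(ut > 0)
}

#' Global weighted clustering coefficient (Onnela)
#'
#' Per-node weighted clustering on weights normalized by the matrix
#' maximum: `C_i = (2 / (k_i (k_i - 1))) * sum_{j<h} (w_ij w_ih w_jh)^(1/3)`
#' with `w` the normalized weights. Nodes with degree < 2 contribute 0. The
#' global value is the mean over all nodes.
#'
#' @param W symmetric non-negative matrix with zero diagonal.
#' @return mean clustering coefficient.
#' @export
clustering_onnela <- function(W) {
  check_that(is.matrix(W) && nrow(W) == ncol(W), "W must be square")
  check_that(all(W >= 0), "negative weights are not allowed")
  mx <- max(W)
  if (mx == 0) {
    warning("all-zero matrix: clustering coefficient is 0", call. = FALSE)
    return(0)
  }
  Wn <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  num <- diag(Wn %*% Wn %*% Wn)         # 2 * sum over j<h triangles
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

#' Newman weighted modularity with a resolution parameter
#'
#' `Q = (1/2m) * sum_ij [ w_ij - gamma * s_i s_j / (2m) ] * delta(c_i, c_j)`
#' with `s` node strengths and `m` the total edge weight.
#'
#' @param W symmetric non-negative matrix with zero diagonal.
#' @param membership integer/character module assignment covering all nodes.
#' @param gamma resolution parameter.
#' @return modularity Q.
#' @export
modularity_q <- function(W, membership, gamma = 1) {
  check_that(is.matrix(W) && nrow(W) == ncol(W), "W must be square")
  check_that(length(membership) == nrow(W),
             "membership must cover all %d nodes", nrow(W))
  two_m <- sum(W)
  check_that(two_m > 0, "empty graph: modularity undefined")
  s <- rowSums(W)
  comm <- as.integer(factor(membership))
  q <- 0
  for (c in unique(comm)) {
    idx <- comm == c
    q <- q + sum(W[idx, idx]) - gamma * sum(s[idx])^2 / two_m
  }
  q / two_m
}

#' Consensus community detection
#'
#' Runs `n_runs` seeded Louvain optimizations at resolution `gamma`, forms
#' the co-assignment agreement matrix, zeroes entries below `tau`,
#' re-clusters the agreement matrix with the same procedure, and iterates
#' until every run returns the same partition (at most `max_iter` rounds).
#'
#' @param W symmetric non-negative matrix with zero diagonal.
#' @param gamma resolution parameter passed to Louvain.
#' @param n_runs Louvain restarts per round.
#' @param tau agreement threshold in \[0, 1\].
#' @param seed integer seed; deterministic given it.
#' @param max_iter maximum consensus rounds.
#' @return list with `membership` (integer vector) and `q`, the modularity
#'   of the consensus partition on the original `W` at `gamma`.
#' @export
consensus_partition <- function(W, gamma = 1, n_runs = 100L, tau = 0.5,
                                seed = 1L, max_iter = 20L) {
  check_that(is.matrix(W) && nrow(W) == ncol(W), "W must be square")
  n <- nrow(W)
  louvain_runs <- function(A, runs) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    lapply(seq_len(runs), function(i) {
      as.integer(igraph::membership(
        igraph::cluster_louvain(g, resolution = gamma)))
    })
  }
  with_rng(seed, {
    A <- W
    for (round in seq_len(max_iter)) {
      runs <- louvain_runs(A, n_runs)
      first <- runs[[1]]
      identical_all <- all(vapply(runs, function(r) {
        # same partition up to label permutation
        length(unique(paste(r, first))) == length(unique(r)) &&
          length(unique(r)) == length(unique(first))
      }, logical(1)))
      if (identical_all) {
        return(list(membership = first, q = modularity_q(W, first, gamma)))
      }
      D <- matrix(0, n, n)
      for (r in runs) D <- D + outer(r, r, "==")
      D <- D / n_runs
      D[D < tau] <- 0
      diag(D) <- 0
      A <- D
    }
    agree <- D[upper.tri(D)]
    agree <- agree[agree > 0 & agree < 1]
    stop(sprintf(paste0("consensus clustering did not converge in %d rounds ",
                        "(agreement entropy %.3f over %d undecided pairs)"),
                 max_iter,
                 if (length(agree)) -mean(agree * log(agree) +
                                            (1 - agree) * log(1 - agree)) else 0,
                 length(agree)), call. = FALSE)
  })
}

#' Global strength-normalized communicability
#'
#' Mean off-diagonal entry of the matrix exponential of
#' `S^(-1/2) W S^(-1/2)` with `S` the diagonal strength matrix
#' (Crofts-Higham normalization). Isolated nodes are excluded from the
#' normalization and the mean. Invariant to a positive rescaling of all
#' weights.
#'
#' @param W symmetric non-negative matrix with zero diagonal.
#' @return global communicability (>= 0); 0 for an empty graph.
#' @export
communicability_global <- function(W) {
  check_that(is.matrix(W) && nrow(W) == ncol(W), "W must be square")
  check_that(all(W >= 0), "negative weights are not allowed")
  s <- rowSums(W)
  keep <- s > 0
  if (!any(keep)) return(0)
  Wk <- W[keep, keep, drop = FALSE]
  d <- 1 / sqrt(s[keep])
  A <- Wk * outer(d, d)
  e <- eigen(A, symmetric = TRUE)
  E <- e$vectors %*% (exp(e$values) * t(e$vectors))
  mean(E[upper.tri(E)])
}

#' Per-participant graph metrics
#'
#' Computes, for every connectome in the set: global density, Onnela
#' clustering, modularity at the a-priori 8-module partition (the atlas's
#' seven cortical networks plus SUB), consensus modularity at each
#' requested gamma, and global communicability.
#'
#' @param connectomes a `connectome_set`.
#' @param atlas atlas table supplying the a-priori partition.
#' @param gammas resolutions for consensus modularity.
#' @param n_runs,tau consensus-clustering controls (see
#'   [consensus_partition()]).
#' @param seed integer seed for the consensus runs.
#' @return data frame, one row per participant: `participant_id`,
#'   `density`, `clustering`, `modularity_apriori`,
#'   `consensus_q_<gamma>`..., `communicability`.
#' @export
graph_metrics <- function(connectomes, atlas, gammas = c(1, 1.25, 1.5),
                          n_runs = 100L, tau = 0.5, seed = 1L) {
  stopifnot(inherits(connectomes, "connectome_set"))
  validate_atlas(atlas, n_nodes = connectomes$n_nodes)
  partition <- atlas$network[order(atlas$node_id)]
  ids <- connectomes$participant_ids
  rows <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    W <- connectomes$matrices[[ids[s]]]
    row <- list(
      participant_id = ids[s],
      density = graph_density(W),
      clustering = clustering_onnela(W),
      modularity_apriori = modularity_q(W, partition, gamma = 1)
    )
    for (g in gammas) {
      cp <- consensus_partition(W, gamma = g, n_runs = n_runs, tau = tau,
                                seed = derive_seed(seed, paste0("consensus", g, ids[s])))
      row[[sprintf("consensus_q_%s", format(g))]] <- cp$q
    }
    row$communicability <- communicability_global(W)
    rows[[s]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Metric-WMH association tables
#'
#' For every metric column: an unadjusted OLS regression of the metric on
#' log global WMH, and an adjusted model additionally controlling for age
#' and fluid cognition; both report the unstandardized coefficient `b`, the
#' standardized coefficient `beta`, 95% confidence intervals, and model
#' R^2. A companion Pearson/FDR correlation table relates each metric to
#' age, fluid cognition, and log global WMH (one FDR family per predictor).
#'
#' @param metrics data frame from [graph_metrics()].
#' @param phenotypes data frame with `participant_id`, `age_years`, a fluid
#'   cognition column, and the WMH volume column.
#' @param wmh_col name of the WMH volume column (log is taken internally).
#' @param fluid_col name of the fluid-cognition column.
#' @return list of class `metrics_assoc` with `regressions` and
#'   `correlations` data frames.
#' @export
metrics_regressions <- function(metrics, phenotypes,
                                wmh_col = "wmh_global_k07",
                                fluid_col = "fluid") {
  check_that(identical(metrics$participant_id, phenotypes$participant_id),
             "metrics and phenotypes participant ids are misaligned")
  lw <- log_wmh(phenotypes[[wmh_col]])
  age <- phenotypes$age_years
  fluid <- phenotypes[[fluid_col]]
  check_that(!is.null(fluid), "fluid-cognition column '%s' not found", fluid_col)
  metric_cols <- setdiff(names(metrics), "participant_id")
  fit_row <- function(yv, design, label, mname) {
    fit <- stats::lm(yv ~ ., data = design)
    sm <- summary(fit)
    ci <- stats::confint(fit)["x", ]
    b <- stats::coef(fit)[["x"]]
    beta <- b * stats::sd(design$x) / stats::sd(yv)
    data.frame(metric = mname, model = label, b = b,
               ci_low = ci[1], ci_high = ci[2],
               beta = beta, r_squared = sm$r.squared,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  regs <- do.call(rbind, lapply(metric_cols, function(mc) {
    yv <- metrics[[mc]]
    rbind(
      fit_row(yv, data.frame(x = lw), "unadjusted", mc),
      fit_row(yv, data.frame(x = lw, age = age, fluid = fluid), "adjusted", mc)
    )
  }))
  dat <- cbind(metrics[metric_cols],
               data.frame(age_years = age, fluid = fluid, log_wmh = lw))
  pairs <- do.call(rbind, lapply(c("age_years", "fluid", "log_wmh"), function(p) {
    data.frame(x = metric_cols, y = p, family = paste0("metrics_vs_", p),
               stringsAsFactors = FALSE)
  }))
  cors <- correlation_table(dat, pairs)
  structure(list(regressions = regs, correlations = cors),
            class = "metrics_assoc")
}

#' @export
print.metrics_assoc <- function(x, ...) {
  cat("Graph-metric association tables\n")
  print(x$regressions, digits = 3)
  invisible(x)
}
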