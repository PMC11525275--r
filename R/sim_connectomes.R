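#' Apply the streamline-count threshold
#'
#' Entries below `min_count` streamlines are set to zero; all others are
#' retained unchanged. Symmetry of the input is preserved.
#'
#' @param mat square non-negative matrix of streamline counts.
#' @param min_count minimum retained count (default 3).
#' @return thresholded matrix.
#' @examples
#' apply_streamline_threshold(matrix(c(0, 2, 2, 0), 2))
#' @export
apply_streamline_threshold <- function(mat, min_count = 3) {
  check_that(is.matrix(mat) && nrow(mat) == ncol(mat),
             "input must be a square matrix (got %d x %d)",
             NROW(mat), NCOL(mat))
  mat[mat < min_count] <- 0
  mat
}

#' Simulate a stack of structural connectomes
#'
#' Generates one symmetric 246 x 246 weighted connectome per participant
#' under a planted-signal model:
#'
#' 1. A group baseline of expected streamline counts `W0` is drawn once:
#'    log-normal edge weights on a sparse support, with within-lobe edges
#'    enriched, and the support fraction calibrated so that the mean
#'    post-threshold density is approximately `base_density_target`.
#' 2. The signal mask `S` contains every subcortical-subcortical edge plus a
#'    seeded fraction `signal_cortical_frac` of the SUB-DMN and SUB-FPN
#'    edges, intersected with the baseline support (no signal can be
#'    planted on an edge that carries no streamlines).
#' 3. For participant `s` with standardized WMH latent `b_s`
#'    (`latent_wmh` in the phenotype table), the expected count on edge
#'    `e` is `W0_e * exp(-kappa * b_s)` if `e` is a signal edge and `W0_e`
#'    otherwise, so high WMH load depletes subcortical connectivity.
#' 4. Observed counts are independent Poisson draws, symmetrized, with the
#'    streamline threshold applied (counts below 3 are zeroed).
#'
#' @param phenotypes phenotype table from [simulate_phenotypes()] (must
#'   contain `participant_id` and `latent_wmh`).
#' @param atlas atlas table from [make_atlas()].
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed + 1`).
#' @return an object of class `connectome_set`: list with
#'   `participant_ids`, `matrices` (named list of symmetric matrices),
#'   `signal_mask` (logical edge vector in [edge_map()] order),
#'   `edge_map`, and `n_nodes`.
#' @export
simulate_connectomes <- function(phenotypes, atlas, config = sim_config(),
                                 seed = config$seed + 1L) {
  validate_atlas(atlas)
  check_that(is.data.frame(phenotypes) &&
               all(c("participant_id", "latent_wmh") %in% names(phenotypes)),
             "phenotypes must contain participant_id and latent_wmh columns")
  check_that(nrow(phenotypes) >= 1, "phenotype table is empty")
  n_nodes <- nrow(atlas)
  em <- edge_map(n_nodes)
  m <- nrow(em)
  ord <- order(atlas$node_id)
  lobe <- atlas$lobe[ord]
  network <- atlas$network[ord]
  li <- lobe[em$i + 1L]; lj <- lobe[em$j + 1L]
  ni <- network[em$i + 1L]; nj <- network[em$j + 1L]

  with_rng(seed, {
    # --- group baseline ------------------------------------------------
    # block-structured support: cortical within-lobe and within-network
    # edges enriched (anatomical communities), subcortical-cortical edges
    # mildly enriched (hub-like basal ganglia/thalamus), subcortical-
    # subcortical support sparser so subcortical nodes sit below average
    # strength -- the regime in which aging-related subcortical edge loss
    # increases segregation (modularity up) while pruning communication
    # paths (communicability down), as in adult-lifespan samples
    lambda_all <- exp(stats::rnorm(m, meanlog_baseline(), sdlog_baseline()))
    rel_p <- rep(1, m)
    cort_lobe <- li == lj & li != "Subcortical"
    rel_p[cort_lobe] <- rel_p[cort_lobe] * 3
    cort_net <- ni == nj & ni != "SUB"
    rel_p[cort_net] <- rel_p[cort_net] * 3
    rel_p[ni == "SUB" & nj == "SUB"] <- 0.5
    sub_cort <- xor(ni == "SUB", nj == "SUB")
    rel_p[sub_cort] <- rel_p[sub_cort] * 1.5
    # calibrate the support fraction so that mean post-threshold density
    # approximates the target: retention of a present edge is P(Pois >= 3)
    retain <- mean(stats::ppois(2, lambda_all, lower.tail = FALSE))
    target_presence <- min(1, config$base_density_target / retain)
    rel_n <- rel_p / mean(rel_p)
    # solve the support scale accounting for capped enriched blocks
    f <- stats::uniroot(function(f) mean(pmin(1, f * rel_n)) - target_presence,
                        c(1e-6, 1 / min(rel_n)), tol = 1e-10)$root
    p_edge <- pmin(1, f * rel_n)
    present <- stats::runif(m) < p_edge
    W0 <- ifelse(present, lambda_all, 0)

    # --- planted signal mask -------------------------------------------
    sub_sub <- ni == "SUB" & nj == "SUB"
    sub_x <- function(x) (ni == "SUB" & nj == x) | (ni == x & nj == "SUB")
    mask <- sub_sub
    for (netw in c("DMN", "FPN")) {
      cand <- which(sub_x(netw))
      take <- sample(cand, size = round(config$signal_cortical_frac * length(cand)))
      mask[take] <- TRUE
    }
    # signal exists only where baseline support does: an absent edge's
    # expected count stays zero under any decay
    mask <- mask & present

    # --- per-subject Poisson draws -------------------------------------
    b <- as.numeric(scale(phenotypes$latent_wmh))
    kappa <- config$signal_edge_decay
    mats <- vector("list", nrow(phenotypes))
    for (s in seq_len(nrow(phenotypes))) {
      lam <- W0
      lam[mask] <- lam[mask] * exp(-kappa * b[s])
      counts <- stats::rpois(m, lam)
      counts[counts < 3] <- 0L
      mats[[s]] <- devectorize(counts, n_nodes)
    }
    names(mats) <- phenotypes$participant_id
    structure(list(
      participant_ids = phenotypes$participant_id,
      matrices = mats,
      signal_mask = mask,
      edge_map = em,
      n_nodes = n_nodes
    ), class = "connectome_set")
  })
}

# baseline log-normal scale of expected streamline counts: median ~ 20
# streamlines with wide spread, so almost all present edges survive the
# threshold while a tail of weak edges does not
meanlog_baseline <- function() 3.0
sdlog_baseline <- function() 0.9

#' Validate a connectome set
#'
#' Asserts the structural invariants of a connectome stack: symmetry to
#' machine precision, zero diagonal, non-negative entries, and no entry in
#' the open interval (0, 3) after streamline thresholding.
#'
#' @param connectomes a `connectome_set`.
#' @return `connectomes`, invisibly, or an error naming the first offender.
#' @export
validate_connectome_set <- function(connectomes) {
  stopifnot(inherits(connectomes, "connectome_set"))
  for (id in connectomes$participant_ids) {
    W <- connectomes$matrices[[id]]
    check_that(max(abs(W - t(W))) == 0, "matrix %s is not symmetric", id)
    check_that(all(diag(W) == 0), "matrix %s has a nonzero diagonal", id)
    check_that(all(W >= 0), "matrix %s has negative entries", id)
    check_that(!any(W > 0 & W < 3),
               "matrix %s has sub-threshold entries in (0, 3)", id)
  }
  invisible(connectomes)
}

#' @export
print.connectome_set <- function(x, ...) {
  dens <- mean(vapply(x$matrices, graph_density, numeric(1)))
  cat(sprintf("connectome_set: %d participants, %d nodes, %d edges/map\n",
              length(x$participant_ids), x$n_nodes, nrow(x$edge_map)))
  cat(sprintf("  planted signal edges: %d; mean density %.3f\n",
              sum(x$signal_mask), dens))
  invisible(x)
}
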