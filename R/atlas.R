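#' @keywords internal
LOBE_COUNTS <- c(
  Frontal = 70, Temporal = 40, Parietal = 38, Insular = 12,
  Limbic = 14, Occipital = 36, Subcortical = 36
)

#' @keywords internal
CORTICAL_NETWORKS <- c("DMN", "DAN", "FPN", "LN", "SMN", "VAN", "VIS")

#' Generate a fixture brain atlas table
#'
#' Builds a 246-node atlas (210 cortical + 36 subcortical) with hemisphere,
#' lobe, and intrinsic-network labels matching the node bookkeeping of a
#' standard whole-brain parcellation: seven anatomical lobes with fixed
#' counts (Frontal 70, Temporal 40, Parietal 38, Insular 12, Limbic 14,
#' Occipital 36, Subcortical 36), seven functionally defined cortical
#' networks assigned roughly evenly across the 210 cortical nodes, and an
#' eighth SUB network holding exactly the subcortical nodes.
#'
#' The real parcellation's node list and network assignments are not
#' distributed with the package; this seeded stand-in reproduces the counts
#' and label structure that all downstream edge masks depend on. A
#' user-supplied atlas read with [read_atlas()] overrides it.
#'
#' @param seed integer seed controlling the network shuffle and node volumes.
#' @return a `data.frame` with columns `node_id` (0-based, contiguous),
#'   `name`, `hemisphere` (`"L"`/`"R"`), `lobe`, `network`, `volume_mm3`.
#' @examples
#' atlas <- make_atlas(seed = 1)
#' table(atlas$lobe)
#' @export
make_atlas <- function(seed = 1L) {
  lobes <- rep(names(LOBE_COUNTS), times = LOBE_COUNTS)
  n <- length(lobes)           # 246
  n_cortical <- sum(LOBE_COUNTS[names(LOBE_COUNTS) != "Subcortical"])
  with_rng(seed, {
    network <- character(n)
    pool <- rep(CORTICAL_NETWORKS, length.out = n_cortical)
    network[lobes != "Subcortical"] <- sample(pool)
    network[lobes == "Subcortical"] <- "SUB"
    volume <- round(exp(stats::rnorm(n, mean = 7.6, sd = 0.45)), 1)
    hemisphere <- rep(c("L", "R"), length.out = n)
    atlas <- data.frame(
      node_id = 0:(n - 1L),
      name = sprintf("%s_%s_%03d", substr(lobes, 1, 3), hemisphere, 0:(n - 1L)),
      hemisphere = hemisphere,
      lobe = lobes,
      network = network,
      volume_mm3 = volume,
      stringsAsFactors = FALSE
    )
    validate_atlas(atlas)
    atlas
  })
}

#' Validate an atlas table
#'
#' Checks the structural invariants every stage relies on: unique,
#' contiguous 0-based node ids; allowed lobe and network labels; and the
#' SUB network coinciding exactly with the subcortical lobe.
#'
#' @param atlas a `data.frame` as returned by [make_atlas()] or [read_atlas()].
#' @param n_nodes expected node count (`NULL` to accept any).
#' @return `atlas`, invisibly, on success; otherwise an error.
#' @export
validate_atlas <- function(atlas, n_nodes = NULL) {
  need <- c("node_id", "hemisphere", "lobe", "network")
  check_that(all(need %in% names(atlas)),
             "atlas is missing columns: %s",
             paste(setdiff(need, names(atlas)), collapse = ", "))
  n <- nrow(atlas)
  if (!is.null(n_nodes)) {
    check_that(n == n_nodes, "atlas has %d rows, expected %d", n, n_nodes)
  }
  check_that(!anyDuplicated(atlas$node_id) &&
               all(sort(atlas$node_id) == 0:(n - 1L)),
             "atlas node_id must be unique and contiguous from 0")
  check_that(all(atlas$lobe %in% names(LOBE_COUNTS)),
             "unknown lobe labels: %s",
             paste(unique(setdiff(atlas$lobe, names(LOBE_COUNTS))), collapse = ", "))
  check_that(all(atlas$network %in% c(CORTICAL_NETWORKS, "SUB")),
             "unknown network labels: %s",
             paste(unique(setdiff(atlas$network, c(CORTICAL_NETWORKS, "SUB"))), collapse = ", "))
  check_that(identical(atlas$network == "SUB", atlas$lobe == "Subcortical"),
             "network must be SUB exactly for subcortical-lobe nodes")
  invisible(atlas)
}
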