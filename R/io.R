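#' Read and write atlas, phenotype, and connectome files
#'
#' The on-disk dialect is deliberately plain: the atlas is a TSV with a
#' header; phenotypes a CSV with a header; each connectome a full square
#' TSV matrix with no header, one file per participant named
#' `<participant_id>.tsv`.
#'
#' @param path file path.
#' @return `read_atlas`: a validated atlas data frame. `read_phenotypes`: a
#'   phenotype data frame. `read_connectome_dir`: a `connectome_set`.
#' @name wmh_io
NULL

#' @rdname wmh_io
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_atlas(atlas)
  atlas
}

#' @rdname wmh_io
#' @param atlas atlas table.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname wmh_io
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that("participant_id" %in% names(ph),
             "phenotype file lacks a participant_id column")
  ph
}

#' @rdname wmh_io
#' @param phenotypes phenotype table.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname wmh_io
#' @param dir directory of `<participant_id>.tsv` matrix files.
#' @param ids participant ids to load (default: from the phenotype table or
#'   all files present).
#' @param n_nodes expected matrix dimension; matrices of any other size are
#'   rejected (override when using a non-246-node atlas).
#' @export
read_connectome_dir <- function(dir, ids = NULL, n_nodes = 246L) {
  check_that(dir.exists(dir), "connectome directory '%s' does not exist", dir)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  avail <- sub("\\.tsv$", "", basename(files))
  if (is.null(ids)) ids <- avail
  missing <- setdiff(ids, avail)
  check_that(length(missing) == 0,
             "connectome files missing for participant(s): %s",
             paste(missing, collapse = ", "))
  mats <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    f <- file.path(dir, paste0(ids[s], ".tsv"))
    W <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    dimnames(W) <- NULL
    check_that(nrow(W) == n_nodes && ncol(W) == n_nodes,
               "%s: matrix is %d x %d, expected %d x %d",
               basename(f), nrow(W), ncol(W), n_nodes, n_nodes)
    asym <- abs(W - t(W))
    if (max(asym) > 1e-8) {
      cell <- sort(which(asym == max(asym), arr.ind = TRUE)[1, ])
      stop(sprintf("%s: asymmetric at cell (%d, %d): %g vs %g",
                   basename(f), cell[1], cell[2],
                   W[cell[1], cell[2]], W[cell[2], cell[1]]), call. = FALSE)
    }
    check_that(all(W >= 0), "%s: negative entries", basename(f))
    mats[[s]] <- W
  }
  names(mats) <- ids
  structure(list(
    participant_ids = ids,
    matrices = mats,
    signal_mask = NULL,
    edge_map = edge_map(n_nodes),
    n_nodes = n_nodes
  ), class = "connectome_set")
}

#' @rdname wmh_io
#' @param connectomes a `connectome_set`.
#' @export
write_connectome_dir <- function(connectomes, dir) {
  stopifnot(inherits(connectomes, "connectome_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in connectomes$participant_ids) {
    utils::write.table(connectomes$matrices[[id]],
                       file.path(dir, paste0(id, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
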