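#' Canonical edge ordering for vectorized connectomes
#'
#' Enumerates the upper-triangle node pairs `(i, j)`, `i < j`, of an
#' `n_nodes`-node network in strictly lexicographic order. For 246 nodes the
#' map has 246 * 245 / 2 = 30135 entries, the length of every vectorized
#' connectome.
#'
#' @param n_nodes number of nodes.
#' @return a `data.frame` with 0-based columns `i`, `j` (`i < j`).
#' @examples
#' head(edge_map(4))
#' @export
edge_map <- function(n_nodes = 246L) {
  check_that(n_nodes >= 2, "need at least 2 nodes")
  j <- sequence(seq_len(n_nodes - 1L))            # column index per lower-tri cell
  # lexicographic (i, j), i < j: for i = 0 .. n-2, j = i+1 .. n-1
  i <- rep(0:(n_nodes - 2L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(0:(n_nodes - 2L), function(a) (a + 1L):(n_nodes - 1L)))
  data.frame(i = i, j = j)
}

#' Vectorize a symmetric connectivity matrix
#'
#' Maps a symmetric matrix to its upper-triangle edge vector in the
#' lexicographic order of [edge_map()], and back. `devectorize` is the exact
#' inverse (round-trip identity).
#'
#' @param mat symmetric numeric matrix.
#' @param tol maximum tolerated asymmetry `max(abs(mat - t(mat)))`.
#' @return `vectorize`: numeric vector of length `n(n-1)/2`;
#'   `devectorize`: symmetric matrix with zero diagonal.
#' @examples
#' W <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
#' vectorize(W)
#' all(devectorize(vectorize(W), 3) == W)
#' @export
vectorize <- function(mat, tol = 1e-8) {
  check_that(is.matrix(mat) && nrow(mat) == ncol(mat),
             "input must be a square matrix")
  asym <- max(abs(mat - t(mat)))
  check_that(asym <= tol,
             "matrix is asymmetric (max |W - t(W)| = %.3g exceeds tol %.3g)", asym, tol)
  # for a symmetric matrix the column-major lower triangle enumerates the
  # upper-triangle pairs (i, j), i < j, in lexicographic order
  mat[lower.tri(mat)]
}

#' @rdname vectorize
#' @param v edge vector of length `n_nodes (n_nodes - 1) / 2`.
#' @param n_nodes number of nodes.
#' @export
devectorize <- function(v, n_nodes = 246L) {
  m <- n_nodes * (n_nodes - 1L) / 2
  check_that(length(v) == m,
             "edge vector has length %d, expected %d for %d nodes",
             length(v), m, n_nodes)
  out <- matrix(0, n_nodes, n_nodes)
  out[lower.tri(out)] <- v
  out + t(out)
}

#' Stack a connectome set into an n x m edge matrix
#'
#' @param connectomes a `connectome_set` (see [simulate_connectomes()]).
#' @return numeric matrix, one row per participant, one column per edge in
#'   [edge_map()] order; row names are participant ids.
#' @export
connectome_edges <- function(connectomes) {
  stopifnot(inherits(connectomes, "connectome_set"))
  X <- t(vapply(connectomes$matrices, vectorize,
                numeric(nrow(connectomes$matrices[[1]]) *
                          (nrow(connectomes$matrices[[1]]) - 1L) / 2)))
  rownames(X) <- connectomes$participant_ids
  X
}
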