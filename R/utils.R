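#' Round half away from zero (for positive inputs: round half up)
#'
#' Feature-selection sizes are defined as `round_half_up(fraction * n)`;
#' base R's `round()` rounds half to even, which gives 1,000 instead of
#' 1,001 at 15% of 6,670, so the convention is pinned here.
#'
#' @param x numeric vector, assumed non-negative.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Number of unique region pairs (edges) for a parcellation
#'
#' @param n_rois number of regions of interest.
#' @return `n_rois * (n_rois - 1) / 2`.
#' @examples
#' n_edges(116)  # 6670
#' @export
n_edges <- function(n_rois) {
  stopifnot(is.numeric(n_rois), n_rois >= 2)
  as.integer(n_rois * (n_rois - 1) / 2)
}

#' Canonical edge ordering for the strict lower triangle
#'
#' Edge k maps to ROI pair (row, col) with row > col, traversed
#' column-major (all pairs of column 1 first, then column 2, ...). This is
#' the order `m[lower.tri(m)]` uses, and it is identical for every subject;
#' all edge-indexed outputs in the package refer to it.
#'
#' @param n_rois number of regions.
#' @return data.frame with columns `edge`, `row`, `col`.
#' @export
edge_index <- function(n_rois) {
  stopifnot(n_rois >= 2)
  idx <- which(lower.tri(matrix(0, n_rois, n_rois)), arr.ind = TRUE)
  data.frame(edge = seq_len(nrow(idx)),
             row = as.integer(idx[, "row"]),
             col = as.integer(idx[, "col"]))
}

#' Edge column names (edge_0001, ...)
#' @keywords internal
edge_names <- function(n_edge) {
  sprintf(paste0("edge_%0", max(4L, nchar(n_edge)), "d"), seq_len(n_edge))
}

#' Project a symmetric matrix to the nearest positive-semidefinite
#' correlation matrix
#'
#' Eigenvalues below `eps` are clipped to `eps`, the matrix is rebuilt and
#' rescaled to unit diagonal. Used after perturbing correlation matrices on
#' the Fisher-z scale, which can leave them slightly indefinite.
#'
#' @param m symmetric matrix with unit diagonal (approximately).
#' @param eps smallest admitted eigenvalue.
#' @return a symmetric PSD correlation matrix.
#' @keywords internal
nearest_pd_corr <- function(m, eps = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) {
    diag(m) <- 1
    return(m)
  }
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Counter-based splitting: every stochastic unit (subject, permutation
#' block) gets its own seed derived from the master seed and an index, so
#' outputs are bitwise reproducible and insensitive to evaluation order.
#' Kept strictly below 2^31.
#'
#' @param master master integer seed.
#' @param index non-negative counter.
#' @param stream optional stream discriminator.
#' @keywords internal
derive_seed <- function(master, index, stream = 0L) {
  as.integer((as.numeric(master) %% 1e6 * 1009 +
                as.numeric(index) * 7919 +
                as.numeric(stream) * 104729) %% 2147483629) + 1L
}
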