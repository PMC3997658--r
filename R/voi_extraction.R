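#' First eigenvariate of a set of voxel time series
#'
#' The representative time course of a VOI: each voxel series is
#' mean-centered, the first right singular vector of the voxels x frames
#' matrix is taken, scaled to unit (sample) variance, and sign-fixed so that
#' its correlation with the mean voxel time series is non-negative.
#'
#' @param voxel_ts voxels x frames matrix (>= 1 voxel).
#' @return Numeric vector of length `frames` with unit variance.
#' @export
first_eigenvariate <- function(voxel_ts) {
  voxel_ts <- as.matrix(voxel_ts)
  if (nrow(voxel_ts) < 1L || ncol(voxel_ts) < 2L)
    stopf("need at least 1 voxel and 2 frames")
  xc <- voxel_ts - rowMeans(voxel_ts)
  if (all(abs(xc) < 1e-14)) stopf("degenerate VOI: all voxel series are constant")
  sv <- svd(xc, nu = 0L, nv = 1L)
  v <- sv$v[, 1L]
  mean_ts <- colMeans(xc)
  s <- sum(v * mean_ts)
  if (s < 0) v <- -v
  sdv <- stats::sd(v)
  if (sdv < 1e-14) stopf("degenerate VOI: first component has zero variance")
  v / sdv
}

#' Extract one eigenvariate series per network node
#'
#' Applies [sphere_voxels()] and [first_eigenvariate()] to every node of a
#' network. Subjects carrying node-level series directly (ROI-level records)
#' bypass extraction: their columns are selected by node abbreviation.
#'
#' @param bold X x Y x Z x T array, or a frames x nodes matrix with node
#'   abbreviations as column names (ROI-level shortcut).
#' @param network a [network_model()].
#' @param grid the [voxel_grid()] of `bold` (ignored for ROI-level input).
#' @param mask optional inclusion (e.g. grey-matter) mask passed to
#'   [sphere_voxels()].
#' @return frames x nodes matrix with columns named by node abbrevs and an
#'   attribute `"n_voxels"` (voxel count per node; `NA` for ROI-level input).
#' @export
extract_node_series <- function(bold, network, grid = NULL, mask = NULL) {
  ab <- node_abbrevs(network)
  if (is.matrix(bold)) {
    missing <- setdiff(ab, colnames(bold))
    if (length(missing))
      stopf("ROI-level input lacks node series for: %s", paste(missing, collapse = ", "))
    out <- bold[, ab, drop = FALSE]
    attr(out, "n_voxels") <- stats::setNames(rep(NA_integer_, length(ab)), ab)
    return(out)
  }
  if (!(is.array(bold) && length(dim(bold)) == 4L))
    stopf("bold must be a 4-D array or a frames x nodes matrix")
  if (is.null(grid)) stopf("grid is required for volumetric input")
  nt <- dim(bold)[4]
  flat <- matrix(bold, prod(dim(bold)[1:3]), nt)
  out <- matrix(NA_real_, nt, length(ab), dimnames = list(NULL, ab))
  nv <- stats::setNames(integer(length(ab)), ab)
  for (n in seq_along(network$nodes)) {
    vox <- sphere_voxels(network$nodes[[n]], grid, mask)
    if (length(vox) == 0L)
      stopf("node '%s': sphere contains no voxels after masking", ab[n])
    nv[n] <- length(vox)
    out[, n] <- first_eigenvariate(flat[vox, , drop = FALSE])
  }
  attr(out, "n_voxels") <- nv
  out
}
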