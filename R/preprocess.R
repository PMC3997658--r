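#' Preprocessing configuration
#'
#' Defaults follow common resting-state practice: discard the first 4 frames
#' (scanner saturation), smooth volumes with a 5-mm FWHM Gaussian kernel,
#' remove first- and second-order nuisance effects (6 motion parameters,
#' their first derivatives, and mean grey-matter / white-matter / CSF
#' signals, plus the squares of all 15), and band-pass filter to
#' 0.01-0.08 Hz.
#'
#' @param n_discard number of initial frames to drop (>= 0).
#' @param fwhm Gaussian smoothing kernel full width at half maximum, mm.
#' @param band passband `c(f_low, f_high)` in Hz; must satisfy
#'   `0 <= f_low < f_high < 1 / (2 * TR)`.
#' @param nuisance_order 1 (base regressors only) or 2 (plus their squares).
#' @param filter_nuisance if `TRUE`, band-pass filter the nuisance columns
#'   before regression ("simultaneous" hygiene mode) so that regression
#'   cannot reintroduce filtered-out variance. Default `FALSE` follows the
#'   conventional order regress-then-filter.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(n_discard = 4L, fwhm = 5, band = c(0.01, 0.08),
                           nuisance_order = 2L, filter_nuisance = FALSE) {
  if (!is_number(n_discard) || n_discard < 0) stopf("n_discard must be >= 0")
  if (!is_number(fwhm) || fwhm < 0) stopf("fwhm must be >= 0")
  band <- as.numeric(band)
  if (length(band) != 2L || band[1] < 0 || band[1] >= band[2])
    stopf("band must be c(f_low, f_high) with 0 <= f_low < f_high")
  if (!nuisance_order %in% c(1L, 2L)) stopf("nuisance_order must be 1 or 2")
  structure(list(n_discard = as.integer(n_discard), fwhm = fwhm, band = band,
                 nuisance_order = as.integer(nuisance_order),
                 filter_nuisance = isTRUE(filter_nuisance)),
            class = "preproc_config")
}

#' Discard initial frames
#'
#' Removes the first `n_discard` time points from a series. Works on a
#' frames-by-channels matrix, a vector, or a 4-D array with time last;
#' companion series (motion, tissue means) must be trimmed with the same
#' call so that frame counts stay coherent.
#'
#' @param x vector, frames x k matrix, or X x Y x Z x T array.
#' @param n_discard frames to remove from the start.
#' @return Same type as `x` with `n_discard` fewer frames.
#' @export
discard_initial <- function(x, n_discard = 4L) {
  n_discard <- as.integer(n_discard)
  if (n_discard < 0) stopf("n_discard must be >= 0")
  if (n_discard == 0L) return(x)
  if (is.matrix(x)) {
    if (nrow(x) <= n_discard) stopf("series has %d frames, cannot discard %d", nrow(x), n_discard)
    x[-seq_len(n_discard), , drop = FALSE]
  } else if (is.array(x) && length(dim(x)) == 4L) {
    if (dim(x)[4] <= n_discard) stopf("series has %d frames, cannot discard %d", dim(x)[4], n_discard)
    x[, , , -seq_len(n_discard), drop = FALSE]
  } else if (is.atomic(x) && is.null(dim(x))) {
    if (length(x) <= n_discard) stopf("series has %d frames, cannot discard %d", length(x), n_discard)
    x[-seq_len(n_discard)]
  } else stopf("unsupported input to discard_initial")
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# n x n band matrix applying 1-D convolution with kernel k (zero boundary,
# no renormalization: interior mass is preserved, boundary mass truncated).
kernel_matrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- k[off + r + 1L]
  }
  K
}

conv_axis <- function(arr, axis, k) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a2 <- aperm(arr, perm)
  m <- matrix(a2, nrow = d[axis])
  m <- kernel_matrix(d[axis], k) %*% m
  a2 <- array(m, dim = d[perm])
  aperm(a2, order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Separable per-frame 3-D Gaussian convolution with
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis (in voxel units). Total
#' intensity is preserved for interior voxels; at the boundary mass is
#' truncated (zero padding).
#'
#' @param vol 3-D array or 4-D array with time last.
#' @param fwhm kernel full width at half maximum in mm; 0 is the identity.
#' @param voxel_size voxel edge in mm (scalar or length 3).
#' @return Smoothed array of the same shape.
#' @export
smooth_gaussian <- function(vol, fwhm, voxel_size = 3) {
  if (!is_number(fwhm) || fwhm < 0) stopf("fwhm must be >= 0")
  if (fwhm == 0) return(vol)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  for (ax in 1:3) vol <- conv_axis(vol, ax, gaussian_kernel(sig[ax]))
  vol
}

# Sparse matrix of smoothing weights mapping a flattened volume to smoothed
# values at the given voxels only; exactly equals full smooth_gaussian()
# followed by subsetting (same truncated-Gaussian kernel).
sphere_smooth_weights <- function(grid, voxels, fwhm, voxel_size = NULL) {
  voxel_size <- voxel_size %||% grid$voxel_size
  if (fwhm == 0)
    return(Matrix::sparseMatrix(i = seq_along(voxels), j = voxels,
                                x = rep(1, length(voxels)),
                                dims = c(length(voxels), prod(grid$shape))))
  sig <- fwhm / (2 * sqrt(2 * log(2))) / rep_len(voxel_size, 3L)
  ks <- lapply(sig, gaussian_kernel)
  rr <- vapply(ks, function(k) (length(k) - 1L) %/% 2L, integer(1))
  offs <- as.matrix(expand.grid(dx = -rr[1]:rr[1], dy = -rr[2]:rr[2], dz = -rr[3]:rr[3]))
  w3 <- ks[[1]][offs[, 1] + rr[1] + 1L] * ks[[2]][offs[, 2] + rr[2] + 1L] *
    ks[[3]][offs[, 3] + rr[3] + 1L]
  ijk <- lin_to_arr(grid, voxels)
  n_off <- nrow(offs)
  n_vox <- length(voxels)
  ii <- rep(seq_len(n_vox), each = n_off)
  tgt <- ijk[ii, , drop = FALSE] + offs[rep(seq_len(n_off), times = n_vox), , drop = FALSE]
  ok <- tgt[, 1] >= 1L & tgt[, 1] <= grid$shape[1] &
    tgt[, 2] >= 1L & tgt[, 2] <= grid$shape[2] &
    tgt[, 3] >= 1L & tgt[, 3] <= grid$shape[3]
  Matrix::sparseMatrix(i = ii[ok], j = arr_to_lin(grid, tgt[ok, , drop = FALSE]),
                       x = rep(w3, n_vox)[ok],
                       dims = c(n_vox, prod(grid$shape)))
}

#' Build the nuisance design matrix
#'
#' Columns are: 6 rigid-body motion parameters, their first (backward)
#' differences with the first frame set to 0, 3 tissue mean signals (grey
#' matter, white matter, CSF) -- 15 first-order regressors -- plus, for
#' `order = 2`, the element-wise squares of those 15, and a trailing
#' intercept. All non-intercept columns are mean-centered. Columns that are
#' (numerically) constant or linearly dependent after centering are pruned
#' with a warning.
#'
#' @param motion frames x 6 matrix (tx, ty, tz in mm; rx, ry, rz in rad).
#' @param tissue_means frames x 3 matrix of mean tissue signals.
#' @param order 1 or 2.
#' @return Design matrix with attribute `"pruned"` listing dropped columns.
#' @export
build_nuisance <- function(motion, tissue_means, order = 2L) {
  motion <- as.matrix(motion)
  tissue_means <- as.matrix(tissue_means)
  if (ncol(motion) != 6L) stopf("motion must have 6 columns, got %d", ncol(motion))
  if (ncol(tissue_means) != 3L) stopf("tissue_means must have 3 columns, got %d", ncol(tissue_means))
  if (nrow(motion) != nrow(tissue_means))
    stopf("frame-count mismatch: motion %d vs tissue_means %d", nrow(motion), nrow(tissue_means))
  if (!order %in% c(1L, 2L)) stopf("order must be 1 or 2")
  nt <- nrow(motion)
  dmotion <- rbind(0, diff(motion))
  base <- cbind(motion, dmotion, tissue_means)
  colnames(base) <- c(paste0("mot", 1:6), paste0("dmot", 1:6), c("gm", "wm", "csf"))
  X <- if (order == 2L) {
    sq <- base^2
    colnames(sq) <- paste0(colnames(base), "_sq")
    cbind(base, sq)
  } else base
  X <- sweep(X, 2L, colMeans(X), "-")
  keep <- apply(X, 2L, function(cl) sqrt(sum(cl^2) / max(1, nt - 1)) > 1e-10)
  pruned <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) > 0L) {
    qd <- qr(X)
    if (qd$rank < ncol(X)) {
      drop_idx <- qd$pivot[-seq_len(qd$rank)]
      pruned <- c(pruned, colnames(X)[drop_idx])
      X <- X[, -drop_idx, drop = FALSE]
    }
  }
  if (length(pruned))
    warnf("pruned %d degenerate/collinear nuisance column(s): %s",
          length(pruned), paste(pruned, collapse = ", "))
  X <- cbind(X, intercept = 1)
  attr(X, "pruned") <- pruned
  X
}

#' Regress nuisance variance out of a series
#'
#' Ordinary least-squares residualization of each column of `x` against the
#' nuisance design; residuals are orthogonal to every retained design column.
#'
#' @param x frames x k matrix (voxel or node time series in columns) or
#'   vector.
#' @param nuisance design matrix from [build_nuisance()] (or any frames x p
#'   matrix including an intercept).
#' @return Residual series, same shape as `x`.
#' @export
regress_out <- function(x, nuisance) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  nuisance <- as.matrix(nuisance)
  if (nrow(x) != nrow(nuisance))
    stopf("frame-count mismatch: data %d vs design %d", nrow(x), nrow(nuisance))
  if (ncol(nuisance) >= nrow(x))
    stopf("nuisance design (%d columns) saturates the series (%d frames)",
          ncol(nuisance), nrow(x))
  res <- qr.resid(qr(nuisance), x)
  if (vec) drop(res) else res
}

#' Temporal band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass, order 4 per pass,
#' with odd-reflection padding of at least one period of `f_low` where the
#' series length allows (otherwise `frames - 1`). With `f_low = 0` a low-pass
#' filter is used.
#'
#' @param x vector or frames x k matrix.
#' @param tr sampling interval (repetition time) in seconds.
#' @param band passband `c(f_low, f_high)` in Hz; `f_high` must be below the
#'   Nyquist frequency `1 / (2 * tr)`.
#' @return Filtered series, same shape as `x` (mean effectively removed).
#' @export
bandpass <- function(x, tr, band = c(0.01, 0.08)) {
  if (!is_number(tr) || tr <= 0) stopf("tr must be > 0")
  band <- as.numeric(band)
  nyq <- 1 / (2 * tr)
  if (length(band) != 2L || band[1] < 0 || band[1] >= band[2])
    stopf("band must be c(f_low, f_high) with 0 <= f_low < f_high")
  if (band[2] >= nyq)
    stopf("f_high = %g Hz is at or above Nyquist (%g Hz) for TR = %g s", band[2], nyq, tr)
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  x <- sweep(x, 2L, colMeans(x), "-") # demean first: shrinks filter transients
  bf <- if (band[1] <= 0) {
    signal::butter(4, band[2] / nyq, type = "low")
  } else {
    signal::butter(4, band / nyq, type = "pass")
  }
  n_pad <- if (band[1] > 0) ceiling(1 / (band[1] * tr)) else nrow(x) - 1L
  out <- filtfilt_mat(bf$b, bf$a, x, n_pad)
  dimnames(out) <- dimnames(x)
  if (vec) drop(out) else out
}

# Node-level preprocessing used by the pipeline: discard, nuisance
# regression (order per config), band-pass. `series` frames x nodes;
# motion/tissue trimmed coherently.
preprocess_node_series <- function(series, motion, tissue_means, tr, config) {
  series <- discard_initial(series, config$n_discard)
  motion <- discard_initial(as.matrix(motion), config$n_discard)
  tissue_means <- discard_initial(as.matrix(tissue_means), config$n_discard)
  X <- suppressWarnings(build_nuisance(motion, tissue_means, config$nuisance_order))
  if (config$filter_nuisance) {
    Xf <- X
    nonint <- colnames(X) != "intercept"
    Xf[, nonint] <- bandpass(X[, nonint, drop = FALSE], tr, config$band)
    series <- regress_out(series, cbind(Xf))
  } else {
    series <- regress_out(series, X)
  }
  bandpass(series, tr, config$band)
}
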