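#' Define a spherical volume of interest (VOI)
#'
#' A VOI is a sphere of radius `radius_mm` around a peak coordinate in MNI
#' space (mm). Spheres at meta-analytic activation peaks are the nodes of the
#' networks analysed by this package.
#'
#' @param abbrev short unique label, e.g. `"SGC"`.
#' @param name free-text anatomical name.
#' @param peak_mni numeric length-3 MNI coordinate in mm.
#' @param radius_mm sphere radius in mm (default 5).
#' @return An object of class `voi`.
#' @export
voi <- function(abbrev, name = abbrev, peak_mni, radius_mm = 5) {
  if (!is.character(abbrev) || length(abbrev) != 1L || !nzchar(abbrev))
    stopf("VOI abbrev must be a non-empty string")
  peak_mni <- as.numeric(peak_mni)
  if (length(peak_mni) != 3L || anyNA(peak_mni) || !all(is.finite(peak_mni)))
    stopf("VOI '%s': peak_mni must be a finite 3-vector (got %s)",
          abbrev, paste(peak_mni, collapse = ","))
  if (!is_number(radius_mm) || radius_mm <= 0)
    stopf("VOI '%s': radius must be > 0", abbrev)
  structure(list(abbrev = abbrev, name = name, peak_mni = peak_mni,
                 radius_mm = radius_mm), class = "voi")
}

#' Construct a network model from a list of VOIs
#'
#' The edge set is every unordered pair of nodes, in canonical order
#' (ascending node index), giving `n * (n - 1) / 2` edges.
#'
#' @param name network label.
#' @param nodes list of [voi()] objects (ordered; order fixes edge labels).
#' @return An object of class `network_model` with elements `name`, `nodes`
#'   and `edges` (data frame with columns `i`, `j`, `label`).
#' @export
network_model <- function(name, nodes) {
  if (length(nodes) == 0L) stopf("network '%s' has an empty node list", name)
  if (!all(vapply(nodes, inherits, logical(1), "voi")))
    stopf("nodes must be a list of voi objects")
  ab <- vapply(nodes, `[[`, character(1), "abbrev")
  if (anyDuplicated(ab)) stopf("duplicate VOI abbrevs in network '%s': %s",
                               name, paste(unique(ab[duplicated(ab)]), collapse = ", "))
  n <- length(nodes)
  if (n >= 2L) {
    pairs <- utils::combn(n, 2L)
    edges <- data.frame(i = pairs[1L, ], j = pairs[2L, ],
                        label = paste(ab[pairs[1L, ]], ab[pairs[2L, ]], sep = "-"),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(i = integer(), j = integer(), label = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(name = name, nodes = nodes, edges = edges),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  for (v in x$nodes)
    cat(sprintf("  %-6s (%g, %g, %g) r=%g mm  %s\n", v$abbrev,
                v$peak_mni[1], v$peak_mni[2], v$peak_mni[3], v$radius_mm, v$name))
  invisible(x)
}

node_abbrevs <- function(net) vapply(net$nodes, `[[`, character(1), "abbrev")

#' Load a network definition
#'
#' Loads either one of the built-in networks or a JSON file with schema
#' `{"name", "nodes": [{"abbrev", "name", "peak_mni": [x, y, z], "radius_mm"}]}`.
#' The built-in `"isa"` network is the five-node introspective socio-affective
#' network (SGC, ACC, left amygdala, precuneus, dmPFC); `"control"` is a
#' four-node left-lateralized language network (MTG, IFG, thalamus, angular
#' gyrus). Coordinates are consumed as given; no coordinate-system conversion
#' is performed (inputs are declared MNI mm).
#'
#' @param path_or_builtin `"isa"`, `"control"`, or a path to a network JSON
#'   file.
#' @return A [network_model()].
#' @examples
#' net <- load_network("isa")
#' nrow(net$edges) # 10
#' @export
load_network <- function(path_or_builtin) {
  if (!is.character(path_or_builtin) || length(path_or_builtin) != 1L)
    stopf("path_or_builtin must be a single string")
  path <- path_or_builtin
  if (path %in% c("isa", "control"))
    path <- system.file("extdata", "networks", paste0(path, ".json"),
                        package = "rsfcnet", mustWork = TRUE)
  if (!file.exists(path)) stopf("network file not found: %s", path)
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(spec$nodes) || length(spec$nodes) == 0L)
    stopf("network '%s' defines no nodes", path_or_builtin)
  nodes <- lapply(spec$nodes, function(nd) {
    voi(abbrev = nd$abbrev, name = nd$name %||% nd$abbrev,
        peak_mni = unlist(nd$peak_mni), radius_mm = nd$radius_mm %||% 5)
  })
  network_model(spec$name %||% path_or_builtin, nodes)
}

#' Define a voxel grid
#'
#' A grid is a 3-D lattice of voxels with a 4x4 affine mapping 1-based voxel
#' indices `(i, j, k, 1)` to mm coordinates of voxel centers.
#'
#' @param shape integer length-3 number of voxels per axis.
#' @param voxel_size voxel edge length in mm (isotropic) when `affine` is not
#'   given.
#' @param origin mm coordinate of the center of voxel `(1, 1, 1)` when
#'   `affine` is not given.
#' @param affine optional full 4x4 voxel-to-mm affine (must be invertible).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size = 3, origin = c(0, 0, 0), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stopf("shape must be 3 positive integers")
  if (is.null(affine)) {
    if (!is_number(voxel_size) || voxel_size <= 0) stopf("voxel_size must be > 0")
    affine <- diag(c(rep(voxel_size, 3), 1))
    affine[1:3, 4] <- as.numeric(origin) - voxel_size # center of voxel (1,1,1) at origin
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stopf("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stopf("affine must be invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(shape = shape, affine = affine, voxel_size = vs),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, voxel size %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

# mm coordinates of the centers of the given (1-based) voxel array indices.
voxel_centers <- function(grid, idx_mat) {
  h <- cbind(idx_mat, 1)
  t(grid$affine %*% t(h))[, 1:3, drop = FALSE]
}

# Convert linear (column-major) voxel indices to array indices and back.
lin_to_arr <- function(grid, lin) {
  arrayInd(lin, grid$shape)
}
arr_to_lin <- function(grid, ijk) {
  as.integer((ijk[, 3] - 1) * grid$shape[1] * grid$shape[2] +
               (ijk[, 2] - 1) * grid$shape[1] + ijk[, 1])
}

#' Default synthetic acquisition grid
#'
#' 48 x 56 x 44 voxels at 3 mm, positioned so that all built-in network peaks
#' are covered with a generous (> 12 mm) margin.
#'
#' @return A [voxel_grid()].
#' @export
default_grid <- function() {
  voxel_grid(c(48L, 56L, 44L), voxel_size = 3, origin = c(-99, -84.5, -62))
}

#' Compact grid covering one or more networks
#'
#' Builds the smallest isotropic grid whose voxel centers cover every peak of
#' the given networks with at least `margin_mm` of margin on each side.
#'
#' @param networks a [network_model()] or list of them.
#' @param voxel_size voxel edge in mm.
#' @param margin_mm margin around the peak bounding box in mm.
#' @return A [voxel_grid()].
#' @export
grid_for_networks <- function(networks, voxel_size = 3, margin_mm = 12) {
  if (inherits(networks, "network_model")) networks <- list(networks)
  peaks <- do.call(rbind, lapply(networks, function(net)
    t(vapply(net$nodes, `[[`, numeric(3), "peak_mni"))))
  lo <- apply(peaks, 2, min) - margin_mm
  hi <- apply(peaks, 2, max) + margin_mm
  shape <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  voxel_grid(shape, voxel_size = voxel_size, origin = lo)
}

#' Voxels of a spherical VOI on a grid
#'
#' Returns the linear (column-major) indices of voxels whose *center* lies at
#' Euclidean distance `<= radius_mm` (closed ball, measured in mm through the
#' grid affine) from the VOI peak, optionally intersected with an inclusion
#' mask (e.g. a grey-matter mask).
#'
#' @param voi a [voi()].
#' @param grid a [voxel_grid()].
#' @param mask optional logical/0-1 array matching `grid$shape`, or a vector
#'   of linear voxel indices to intersect with.
#' @return Sorted integer vector of linear voxel indices.
#' @examples
#' g <- voxel_grid(c(21, 21, 21), voxel_size = 3, origin = c(-30, -30, -30))
#' length(sphere_voxels(voi("X", peak_mni = c(0, 0, 0)), g)) # 19
#' @export
sphere_voxels <- function(voi, grid, mask = NULL) {
  inv <- solve(grid$affine)
  pk_vox <- (inv %*% c(voi$peak_mni, 1))[1:3]
  if (any(pk_vox < 0.5) || any(pk_vox > grid$shape + 0.5))
    stopf("VOI '%s': peak (%s) lies outside the grid", voi$abbrev,
          paste(voi$peak_mni, collapse = ", "))
  # candidate bounding box in voxel units
  half <- voi$radius_mm / grid$voxel_size
  lo <- pmax(1L, as.integer(floor(pk_vox - half - 1)))
  hi <- pmin(grid$shape, as.integer(ceiling(pk_vox + half + 1)))
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  ctr <- voxel_centers(grid, ijk)
  d2 <- rowSums(sweep(ctr, 2L, voi$peak_mni, "-")^2)
  keep <- d2 <= voi$radius_mm^2 + 1e-9
  lin <- sort(arr_to_lin(grid, ijk[keep, , drop = FALSE]))
  if (!is.null(mask)) {
    mask_lin <- if (is.array(mask) || is.logical(mask) && length(mask) == prod(grid$shape)) {
      which(as.logical(mask))
    } else {
      as.integer(mask)
    }
    lin <- intersect(lin, mask_lin)
  }
  as.integer(lin)
}
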