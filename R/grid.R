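#' Physical image geometry
#'
#' An `image_grid` describes the regular voxel lattice a mask lives on: the
#' number of voxels along x, y, z, the voxel spacing in millimetres, the
#' physical position of the *center* of voxel (0,0,0), and an orthonormal
#' direction matrix mapping voxel axes to patient axes. All downstream
#' geometry (volumes, centroids, surface distances) is computed in physical
#' millimetres through this mapping, so anisotropic spacing — e.g. the
#' 0.469 x 0.469 x 1.0 mm grids typical of post-contrast T1 MR used for
#' radiosurgery planning — is honored exactly.
#'
#' @param shape Integer triple: voxels along x, y, z.
#' @param spacing Positive numeric triple, mm per voxel.
#' @param origin Numeric triple, mm: physical center of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix (voxel axes in patient axes).
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(64, 64, 32), spacing = c(0.469, 0.469, 1))
#' voxel_to_physical(g, c(0, 0, 0))
#' @export
image_grid <- function(shape, spacing, origin = c(0, 0, 0),
                       direction = diag(3)) {
  shape <- as.integer(round(shape))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three positive integers", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive reals (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite reals (mm)", call. = FALSE)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` must be orthonormal (within 1e-6)", call. = FALSE)
  structure(
    list(shape = shape, spacing = spacing, origin = origin,
         direction = direction),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel volume of a grid
#'
#' @param grid An [image_grid()].
#' @return Volume of one voxel in mm^3.
#' @export
voxel_volume_mm3 <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  prod(grid$spacing)
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("points must have 3 columns", call. = FALSE)
    p
  } else {
    matrix(as.numeric(p), ncol = 3L)
  }
}

#' Map voxel indices to physical coordinates
#'
#' Voxel indices are 0-based and may be fractional; the map is affine:
#' `x = direction %*% (ijk * spacing) + origin`.
#'
#' @param grid An [image_grid()].
#' @param ijk 0-based voxel coordinates: length-3 vector or n x 3 matrix.
#' @return n x 3 matrix of physical coordinates in mm.
#' @export
voxel_to_physical <- function(grid, ijk) {
  stopifnot(inherits(grid, "image_grid"))
  ijk <- as_point_matrix(ijk)
  scaled <- sweep(ijk, 2L, grid$spacing, `*`)
  out <- scaled %*% t(grid$direction)
  sweep(out, 2L, grid$origin, `+`)
}

#' Map physical coordinates to (continuous) voxel indices
#'
#' Inverse of [voxel_to_physical()]; returns fractional 0-based voxel
#' coordinates (the direction matrix is orthonormal so its inverse is its
#' transpose).
#'
#' @inheritParams voxel_to_physical
#' @param xyz Physical coordinates in mm: length-3 vector or n x 3 matrix.
#' @return n x 3 matrix of continuous 0-based voxel coordinates.
#' @export
physical_to_voxel <- function(grid, xyz) {
  stopifnot(inherits(grid, "image_grid"))
  xyz <- as_point_matrix(xyz)
  centered <- sweep(xyz, 2L, grid$origin, `-`)
  out <- centered %*% grid$direction   # == t(t(direction) %*% t(centered))
  sweep(out, 2L, grid$spacing, `/`)
}

# 1-based linear array index <-> 0-based (i,j,k), column-major (x fastest).
idx_to_ijk <- function(idx, shape) {
  arrayInd(idx, .dim = shape) - 1L
}

ijk_to_idx <- function(ijk, shape) {
  ijk <- as_point_matrix(ijk)
  as.integer(ijk[, 1] + shape[1] * (ijk[, 2] + shape[2] * ijk[, 3]) + 1)
}

grids_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}
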