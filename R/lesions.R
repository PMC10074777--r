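#' Effective diameter of a volume-equivalent sphere
#'
#' The effective diameter of a lesion is the diameter of the sphere whose
#' volume equals the lesion's: `d = 2 * (3 * V_mm3 / (4 * pi))^(1/3)` with
#' `V_mm3 = 1000 * volume_cc`. It is the size scale used for sensitivity
#' stratification (the 5 / 7.5 / 10 mm thresholds).
#'
#' @param volume_cc Lesion volume(s) in c.c. (cm^3); must be positive.
#' @return Effective diameter(s) in mm.
#' @examples
#' effective_diameter(0.5236)  # ~10 mm
#' @export
effective_diameter <- function(volume_cc) {
  volume_cc <- as.numeric(volume_cc)
  if (any(!is.finite(volume_cc)) || any(volume_cc <= 0))
    stop("`volume_cc` must be positive", call. = FALSE)
  2 * (3 * (1000 * volume_cc) / (4 * pi))^(1 / 3)
}

#' Volume of a sphere with a given effective diameter
#'
#' Inverse of [effective_diameter()].
#'
#' @param diameter_mm Diameter(s) in mm; must be positive.
#' @return Volume(s) in c.c.
#' @export
sphere_volume_cc <- function(diameter_mm) {
  diameter_mm <- as.numeric(diameter_mm)
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0))
    stop("`diameter_mm` must be positive", call. = FALSE)
  (pi * diameter_mm^3 / 6) / 1000
}

# Construct a lesion object from a set of 1-based linear voxel indices.
# Geometry fields (volume, centroid, effective diameter, surface subset)
# are computed eagerly; they are what every metric consumes.
lesion_from_indices <- function(voxel_idx, grid, id = "L1") {
  voxel_idx <- sort(unique(as.integer(voxel_idx)))
  if (length(voxel_idx) == 0L)
    stop("a lesion must contain at least one voxel", call. = FALSE)
  ijk <- idx_to_ijk(voxel_idx, grid$shape)
  xyz <- voxel_to_physical(grid, ijk)
  volume_cc <- length(voxel_idx) * voxel_volume_mm3(grid) / 1000
  surf <- .surface6(voxel_idx - 1L, grid$shape)
  structure(
    list(id = as.character(id),
         voxel_idx = voxel_idx,
         n_voxels = length(voxel_idx),
         grid = grid,
         volume_cc = volume_cc,
         centroid_mm = colMeans(xyz),
         effective_diameter_mm = effective_diameter(volume_cc),
         surface_idx = voxel_idx[surf]),
    class = "lesion"
  )
}

#' @export
print.lesion <- function(x, ...) {
  cat(sprintf(
    "<lesion %s> %d voxels, %.4g c.c., effective diameter %.2f mm\n",
    x$id, x$n_voxels, x$volume_cc, x$effective_diameter_mm))
  invisible(x)
}

#' Extract lesions as 26-connected components
#'
#' Partitions the set voxels of a mask into 26-connected components — the
#' standard foreground connectivity for 3D lesion masks — and returns one
#' lesion object per component with volume (c.c.), physical centroid (mm),
#' effective diameter (mm) and surface voxels (members with at least one
#' 6-neighbor outside the component) populated. Components are ordered
#' deterministically by their minimal (z, y, x) voxel index and labelled
#' `L001`, `L002`, ...
#'
#' @param mask A [label_volume()].
#' @return A list of lesion objects (empty list for an empty mask).
#' @export
connected_components <- function(mask) {
  stopifnot(inherits(mask, "label_volume"))
  idx <- which(mask$voxels)
  if (length(idx) == 0L) return(list())
  labels <- .cc_label26(idx - 1L, mask$grid$shape)
  groups <- split(idx, labels)
  ijk_min <- t(vapply(groups, function(g) {
    m <- idx_to_ijk(g, mask$grid$shape)
    c(min(m[, 3]), min(m[, 2]), min(m[, 1]))
  }, numeric(3)))
  ord <- order(ijk_min[, 1], ijk_min[, 2], ijk_min[, 3])
  groups <- groups[ord]
  lapply(seq_along(groups), function(i) {
    lesion_from_indices(groups[[i]], mask$grid, sprintf("L%03d", i))
  })
}

#' Physical centroid of a lesion
#'
#' Unweighted mean of the member voxels' physical center coordinates. For
#' non-convex shapes (e.g. crescents) the centroid can fall *outside* the
#' lesion; the detection-matching rule handles that case explicitly.
#'
#' @param lesion A lesion object.
#' @param grid Optional [image_grid()]; defaults to the lesion's own grid.
#' @return Length-3 numeric vector, mm.
#' @export
centroid_mm <- function(lesion, grid = NULL) {
  stopifnot(inherits(lesion, "lesion"))
  if (is.null(grid) || grids_equal(grid, lesion$grid))
    return(lesion$centroid_mm)
  colMeans(voxel_to_physical(grid, idx_to_ijk(lesion$voxel_idx, grid$shape)))
}

surface_coords <- function(lesion) {
  voxel_to_physical(lesion$grid,
                    idx_to_ijk(lesion$surface_idx, lesion$grid$shape))
}

#' Directed surface distances between two lesions
#'
#' For every surface voxel of `a`, the minimum Euclidean distance (physical
#' mm) to the surface voxel centers of `b`, and vice versa. These two lists
#' are the substrate of the average Hausdorff distance.
#'
#' @param a,b Lesion objects on the same grid.
#' @param grid Optional grid consistency check.
#' @return `list(a_to_b = ..., b_to_a = ...)` of numeric distance vectors.
#' @export
surface_distances <- function(a, b, grid = NULL) {
  stopifnot(inherits(a, "lesion"), inherits(b, "lesion"))
  if (!grids_equal(a$grid, b$grid))
    stop("lesions live on different grids", call. = FALSE)
  if (!is.null(grid) && !grids_equal(grid, a$grid))
    stop("`grid` does not match the lesions' grid", call. = FALSE)
  ca <- surface_coords(a)
  cb <- surface_coords(b)
  list(a_to_b = as.numeric(.nn_dist(ca, cb)),
       b_to_a = as.numeric(.nn_dist(cb, ca)))
}
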