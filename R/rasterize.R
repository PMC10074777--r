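#' Rasterize planar contours onto a grid
#'
#' Converts stacks of planar polygons into a binary mask: a voxel is set iff
#' its center lies inside an odd number of the polygons assigned to its
#' slice (even-odd rule), so inner contours carve holes. Each polygon is
#' assigned to the nearest grid slice plane; a polygon whose plane is
#' farther than half a slice spacing from every grid plane, or outside the
#' grid's z extent, is a geometry error.
#'
#' Ground-truth and predicted structure sets must be rasterized onto the
#' *same* reference grid for their metrics to be comparable; the evaluation
#' functions check this.
#'
#' @param x A [structure_set()] (all structures are pooled into one mask) or
#'   a list of polygon matrices (n x 3, mm).
#' @param grid The reference [image_grid()].
#' @return A [label_volume()].
#' @examples
#' g <- image_grid(c(30, 30, 3), spacing = c(1, 1, 1), origin = c(0.5, 0.5, 0))
#' sq <- cbind(c(0, 20, 20, 0), c(0, 0, 20, 20), 0)
#' sum(rasterize(list(sq), g)$voxels)  # 400 voxel centers inside
#' @export
rasterize <- function(x, grid) {
  stopifnot(inherits(grid, "image_grid"))
  polys <- if (inherits(x, "structure_set")) {
    unlist(x$structures, recursive = FALSE, use.names = FALSE)
  } else if (is.list(x)) {
    x
  } else {
    stop("`x` must be a structure_set or a list of polygon matrices",
         call. = FALSE)
  }
  mask <- array(FALSE, dim = grid$shape)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  for (poly in polys) {
    poly <- as_point_matrix(poly)
    if (nrow(poly) < 3L)
      stop("polygon has fewer than 3 vertices", call. = FALSE)
    vox <- physical_to_voxel(grid, poly)
    kf <- mean(vox[, 3])
    k <- round(kf)
    if (max(abs(vox[, 3] - k)) > 0.5 + 1e-6)
      stop(sprintf(
        "contour at z = %.3f mm is not within half a slice spacing of a grid plane",
        mean(poly[, 3])), call. = FALSE)
    if (k < 0 || k >= nz)
      stop(sprintf("contour at z = %.3f mm lies outside the grid z extent",
                   mean(poly[, 3])), call. = FALSE)
    i0 <- max(0L, as.integer(floor(min(vox[, 1]))))
    i1 <- min(nx - 1L, as.integer(ceiling(max(vox[, 1]))))
    j0 <- max(0L, as.integer(floor(min(vox[, 2]))))
    j1 <- min(ny - 1L, as.integer(ceiling(max(vox[, 2]))))
    if (i0 > i1 || j0 > j1) next
    is <- i0:i1
    js <- j0:j1
    px <- rep(is, times = length(js))
    py <- rep(js, each = length(is))
    inside <- points_in_polygon_eo(px, py, vox[, 1], vox[, 2])
    if (any(inside)) {
      block <- matrix(inside, nrow = length(is))
      # even-odd across polygons: xor into the accumulated slice
      mask[is + 1L, js + 1L, k + 1L] <- xor(mask[is + 1L, js + 1L, k + 1L],
                                            block)
    }
  }
  label_volume(grid, mask)
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# Points exactly on an edge resolve deterministically by the half-open
# crossing convention.
points_in_polygon_eo <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; yj <- vy[j]
    xi <- vx[i]; xj <- vx[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
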