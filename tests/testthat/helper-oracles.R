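# Brute-force oracles, kept deliberately independent of the package's
# compiled implementations: plain R set arithmetic and all-pairs distances.

# 0-based (i,j,k) for 1-based linear indices of an array with dims `shape`
oracle_ijk <- function(idx, shape) arrayInd(idx, .dim = shape) - 1L

# surface voxels by direct 6-neighbor membership checks
oracle_surface <- function(idx, shape) {
  ijk <- oracle_ijk(idx, shape)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  members <- key(ijk)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  surf <- logical(length(idx))
  for (s in seq_len(nrow(shifts))) {
    nb <- sweep(ijk, 2L, shifts[s, ], `+`)
    outside <- nb[, 1] < 0 | nb[, 1] >= shape[1] |
      nb[, 2] < 0 | nb[, 2] >= shape[2] |
      nb[, 3] < 0 | nb[, 3] >= shape[3]
    surf <- surf | outside | !(key(nb) %in% members)
  }
  idx[surf]
}

oracle_coords <- function(idx, grid) {
  ijk <- oracle_ijk(idx, grid$shape)
  sweep(sweep(ijk, 2L, grid$spacing, `*`) %*% t(grid$direction),
        2L, grid$origin, `+`)
}

# all-pairs directed nearest-neighbor distances
oracle_nn <- function(a, b) {
  vapply(seq_len(nrow(a)), function(p) {
    sqrt(min(colSums((t(b) - a[p, ])^2)))
  }, numeric(1))
}

# average symmetric surface distance from first principles
oracle_avd_mm <- function(idx_a, idx_b, grid) {
  sa <- oracle_coords(oracle_surface(idx_a, grid$shape), grid)
  sb <- oracle_coords(oracle_surface(idx_b, grid$shape), grid)
  mean(c(oracle_nn(sa, sb), oracle_nn(sb, sa)))
}

oracle_dsc <- function(idx_a, idx_b) {
  2 * length(intersect(idx_a, idx_b)) / (length(idx_a) + length(idx_b))
}

# Fixture builders ------------------------------------------------------------

# linear indices of an axis-aligned voxel box, 0-based corner coords inclusive
box_indices <- function(grid, lo, hi) {
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  as.integer(ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3]) + 1)
}

mask_from_indices <- function(grid, idx) {
  arr <- array(FALSE, dim = grid$shape)
  arr[idx] <- TRUE
  label_volume(grid, arr)
}

# voxel-center sphere mask (independent of the contour rasterizer)
sphere_indices <- function(grid, center_mm, radius_mm) {
  shape <- grid$shape
  ctr <- physical_to_voxel(grid, center_mm)[1, ]
  r_vox <- ceiling(radius_mm / grid$spacing) + 1
  lo <- pmax(floor(ctr - r_vox), 0)
  hi <- pmin(ceiling(ctr + r_vox), shape - 1)
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  xyz <- voxel_to_physical(grid, ijk)
  keep <- colSums((t(xyz) - center_mm)^2) <= radius_mm^2
  as.integer(ijk[keep, 1] + shape[1] * (ijk[keep, 2] + shape[2] * ijk[keep, 3]) + 1)
}

# a random connected-ish blob: union of a few voxel spheres in a small grid
random_blob <- function(grid, n_seeds = 3, r_range = c(1.2, 3.5)) {
  idx <- integer(0)
  ext <- grid$shape * grid$spacing
  while (length(idx) == 0L) {
    for (s in seq_len(n_seeds)) {
      ctr <- runif(3, 0.25, 0.75) * ext
      idx <- union(idx, sphere_indices(grid, ctr,
                                       runif(1, r_range[1], r_range[2])))
    }
  }
  sort(idx)
}

# circle-stack contours of a sphere for rasterization tests
sphere_contour_list <- function(center, radius, z_planes, n_vertices = 64) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  out <- list()
  for (z in z_planes) {
    dz <- z - center[3]
    if (abs(dz) >= radius) next
    rho <- sqrt(radius^2 - dz^2)
    out[[length(out) + 1L]] <- cbind(center[1] + rho * cos(theta),
                                     center[2] + rho * sin(theta), z)
  }
  out
}

# union of lesion voxel sets as a label volume
rasterize_to_lv <- function(grid, lesions) {
  mask_from_indices(grid, unlist(lapply(lesions, `[[`, "voxel_idx")))
}
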