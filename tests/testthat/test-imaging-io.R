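test_that("image_grid validates geometry and inverts its affine map", {
  g <- image_grid(c(10, 12, 8), c(0.469, 0.469, 1), origin = c(-5, 3, 1))
  expect_equal(voxel_volume_mm3(g), 0.469 * 0.469 * 1)
  ijk <- rbind(c(0, 0, 0), c(3, 7, 2), c(9, 11, 7))
  expect_equal(physical_to_voxel(g, voxel_to_physical(g, ijk)), ijk,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(voxel_to_physical(g, c(0, 0, 0))[1, ], g$origin)
  expect_error(image_grid(c(10, 10, 10), c(0, 1, 1)), "spacing")
  expect_error(image_grid(c(10, 10, 10), c(1, 1, 1),
                          direction = matrix(1, 3, 3)), "orthonormal")
})

test_that("json-contours structure sets round-trip vertex-identically", {
  sq <- cbind(c(0, 20, 20, 0), c(0, 0, 20, 20), 0)
  tri <- cbind(c(1, 4, 2.5), c(1, 1, 5), 2)
  ss <- structure_set("P001", list(Met_01 = list(sq), Met_02 = list(tri, tri)),
                      frame_of_reference = "FOR-1")
  f <- tempfile(fileext = ".json")
  write_structure_set(ss, f)
  back <- read_structure_set(f)
  expect_s3_class(back, "structure_set")
  expect_identical(back$patient_id, "P001")
  expect_identical(names(back$structures), c("Met_01", "Met_02"))
  expect_identical(lengths(back$structures), c(Met_01 = 1L, Met_02 = 2L))
  expect_equal(back$structures$Met_01[[1]], sq, ignore_attr = TRUE)
  expect_equal(back$structures$Met_02[[2]], tri, ignore_attr = TRUE)
  expect_identical(back$frame_of_reference, "FOR-1")
})

test_that("structure-set errors name the offending structure and file", {
  expect_error(read_structure_set(file.path(tempdir(), "nope.json")),
               "not found")
  expect_error(structure_set("P", list(Bad = list(cbind(1:2, 1:2, 0)))),
               "fewer than 3")
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_structure_set(bad), "parse")
})

test_that("DICOM RTSS round-trips through the pydicom bridge", {
  sq <- cbind(c(0, 20, 20, 0), c(0, 0, 20, 20), 0)
  tri <- cbind(c(1, 4, 2.5), c(1, 1, 5), 2)
  ss <- structure_set("P007", list(Met_01 = list(sq), Met_02 = list(tri)))
  f <- tempfile(fileext = ".dcm")
  write_structure_set(ss, f, dialect = "dicom-rtss")
  back <- read_structure_set(f, dialect = "dicom-rtss")
  expect_identical(back$patient_id, "P007")
  expect_identical(names(back$structures), c("Met_01", "Met_02"))
  # ContourData is serialized as decimal strings at micrometre precision
  expect_equal(back$structures$Met_01[[1]], sq, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("rasterization fills voxel centers by the even-odd rule", {
  g <- image_grid(c(30, 30, 3), c(1, 1, 1), origin = c(0.5, 0.5, 0))
  sq <- cbind(c(0, 20, 20, 0), c(0, 0, 20, 20), 1)
  expect_equal(sum(rasterize(list(sq), g)$voxels), 400)
  inner <- cbind(c(5, 15, 15, 5), c(5, 5, 15, 15), 1)
  lv <- rasterize(list(sq, inner), g)
  expect_equal(sum(lv$voxels), 300)         # the inner square carves a hole
  expect_equal(sum(lv$voxels[, , 2]), 300)  # all on the contour's slice
  expect_error(rasterize(list(cbind(c(0, 20, 20, 0), c(0, 0, 20, 20), 99)), g),
               "z extent")
  off_plane <- cbind(c(0, 20, 20, 0), c(0, 0, 20, 20), c(1, 1, 1, 1.8))
  expect_error(rasterize(list(off_plane), g), "half a slice")
})

test_that("a contoured sphere rasterizes to its analytic volume within 5%", {
  g <- image_grid(c(30, 30, 30), c(1, 1, 1))
  ctr <- c(14.5, 14.5, 14.2)
  lv <- rasterize(sphere_contour_list(ctr, 10, (0:29) * 1), g)
  vol <- sum(lv$voxels) * voxel_volume_mm3(g)
  expect_lt(abs(vol - 4188.79) / 4188.79, 0.05)
})

test_that("rasterization is translation-equivariant and resolution-consistent", {
  shift <- c(3.7, -2.1, 1.0)
  g1 <- image_grid(c(26, 26, 26), c(1, 1, 1))
  g2 <- image_grid(c(26, 26, 26), c(1, 1, 1), origin = shift)
  ctr <- c(12.3, 12.6, 12.5)
  polys1 <- sphere_contour_list(ctr, 8, (0:25) * 1)
  polys2 <- lapply(polys1, function(p) sweep(p, 2L, shift, `+`))
  expect_identical(rasterize(polys1, g1)$voxels, rasterize(polys2, g2)$voxels)

  # halving the spacing changes a convex volume by less than the coarse
  # surface-shell volume
  fine <- image_grid(c(52, 52, 52), c(0.5, 0.5, 0.5))
  polys_f <- sphere_contour_list(ctr, 8, (0:51) * 0.5)
  v_coarse <- rasterize(polys1, g1)
  v_fine <- rasterize(polys_f, fine)
  les <- connected_components(v_coarse)[[1]]
  shell_mm3 <- length(les$surface_idx) * voxel_volume_mm3(g1)
  expect_lt(abs(mask_volume_cc(v_fine) - mask_volume_cc(v_coarse)) * 1000,
            shell_mm3)
})

test_that("NIfTI label volumes round-trip mask and geometry exactly", {
  g <- image_grid(c(12, 10, 8), c(0.469, 0.469, 1.2), origin = c(-20, 5, 2))
  idx <- box_indices(g, c(2, 3, 1), c(6, 6, 4))
  lv <- mask_from_indices(g, idx)
  f <- tempfile(fileext = ".nii")
  write_label_volume(lv, f)
  back <- read_label_volume(f)
  expect_identical(which(back$voxels), which(lv$voxels))
  expect_equal(back$grid$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(back$grid$origin, g$origin, tolerance = 1e-6)
  expect_equal(back$grid$direction, g$direction, tolerance = 1e-6)
  # volume bookkeeping: voxel count times voxel volume (spacing is stored
  # as float32 in the header, so agreement is to float precision)
  expect_equal(mask_volume_cc(back),
               length(idx) * voxel_volume_mm3(g) / 1000, tolerance = 1e-6)
  # empty image
  empty <- label_volume(g)
  f2 <- tempfile(fileext = ".nii")
  write_label_volume(empty, f2)
  expect_equal(sum(read_label_volume(f2)$voxels), 0)
})

test_that("523 unit voxels measure 0.523 c.c.", {
  g <- image_grid(c(20, 20, 20), c(1, 1, 1))
  idx <- seq_len(523)  # any 523 distinct voxels
  expect_equal(mask_volume_cc(mask_from_indices(g, idx)), 0.523)
})

test_that("generator-written structure sets read back with recorded counts", {
  cfg <- simulation_config(seed = 5, patients = 2,
                           grid = list(spacing = c(1, 1, 1),
                                       extent_mm = c(100, 100, 100)))
  dir <- tempfile()
  coh <- generate_cohort(cfg, dir = dir)
  for (pid in names(coh$gt)) {
    back <- read_structure_set(file.path(dir, "gt", paste0(pid, ".json")))
    n_truth <- sum(coh$truth$lesions$patient_id == pid)
    expect_length(back$structures, n_truth)
    expect_identical(lengths(back$structures),
                     lengths(coh$gt[[pid]]$structures))
  }
})
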