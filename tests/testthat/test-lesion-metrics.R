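make_lesion <- function(idx, grid, id = "L1") {
  lesionwise:::lesion_from_indices(idx, grid, id)
}

test_that("DSC follows its set definition and symmetries", {
  g <- image_grid(c(20, 20, 20), c(1, 1, 1))
  a <- box_indices(g, c(1, 1, 1), c(2, 2, 2))        # 8 voxels
  b <- box_indices(g, c(1, 1, 2), c(2, 2, 3))        # 8 voxels, 4 overlap
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, box_indices(g, c(10, 10, 10), c(11, 11, 11))), 0)
  expect_equal(dsc(a, b), 0.5)
  expect_equal(dsc(a, b), dsc(b, a))
  # joint translation invariance (shift both sets by one voxel in z)
  shift <- as.integer(20 * 20)
  expect_equal(dsc(a + shift, b + shift), dsc(a, b))
  expect_error(dsc(integer(0), integer(0)), "undefined")
})

test_that("AVD matches analytic slab and identity cases", {
  g <- image_grid(c(20, 20, 20), c(1, 1, 1))
  les <- make_lesion(box_indices(g, c(2, 2, 2), c(6, 6, 6)), g)
  ident <- avd(les, les)
  expect_equal(ident$avd_mm, 0)
  expect_equal(ident$avd_pct, 0)

  # two parallel 1-voxel-thick slabs of equal size, 3 mm apart
  s1 <- make_lesion(box_indices(g, c(2, 2, 5), c(8, 8, 5)), g)
  s2 <- make_lesion(box_indices(g, c(2, 2, 8), c(8, 8, 8)), g)
  expect_equal(avd(s1, s2)$avd_mm, 3)
  expect_equal(avd(s1, s2)$avd_pct,
               100 * 3 / s1$effective_diameter_mm)
})

test_that("AVD equals the brute-force oracle on random pairs", {
  set.seed(7)
  g <- image_grid(c(13, 13, 13), c(1, 0.7, 1.4))
  for (rep in 1:10) {
    idx_a <- random_blob(g)
    idx_b <- random_blob(g)
    a <- make_lesion(idx_a, g); b <- make_lesion(idx_b, g)
    expect_equal(avd(a, b)$avd_mm, oracle_avd_mm(idx_a, idx_b, g),
                 tolerance = 1e-12)
    # max-of-directed-means variant bounds the symmetric mean from above
    expect_gte(avd(a, b, variant = "max_directed")$avd_mm,
               avd(a, b)$avd_mm - 1e-12)
  }
})

test_that("matching detects by centroid containment, counts FPs by overlap", {
  g <- image_grid(c(30, 30, 30), c(1, 1, 1))
  gt1 <- make_lesion(box_indices(g, c(2, 2, 2), c(7, 7, 7)), g, "G1")
  gt2 <- make_lesion(box_indices(g, c(15, 15, 15), c(20, 20, 20)), g, "G2")

  # identical predictions: all detected, no FP
  mr <- match_lesions(list(gt1, gt2), list(gt1, gt2))
  expect_true(all(mr$matches$detected))
  expect_equal(mr$matches$dsc, c(1, 1))
  expect_equal(mr$fp_count, 0L)

  # fully disjoint prediction: no detection, one FP
  stray <- make_lesion(box_indices(g, c(24, 24, 24), c(26, 26, 26)), g, "S")
  mr2 <- match_lesions(list(gt1), list(stray))
  expect_false(any(mr2$matches$detected))
  expect_equal(mr2$fp_count, 1L)
  expect_identical(mr2$fp_ids, "S")
  expect_true(all(is.na(mr2$matches$dsc)))
})

test_that("overlap without centroid containment is neither detection nor FP", {
  g <- image_grid(c(30, 30, 30), c(1, 1, 1))
  gt1 <- make_lesion(box_indices(g, c(2, 2, 2), c(7, 7, 7)), g, "G1")
  # slab sharing exactly one face-layer of voxels with gt1; its centroid
  # sits far outside gt1
  slab_idx <- box_indices(g, c(7, 2, 2), c(16, 7, 7))
  slab <- make_lesion(slab_idx, g, "S")
  overlap <- intersect(slab_idx, gt1$voxel_idx)
  expect_gt(length(overlap), 0)
  ctr_vox <- round(physical_to_voxel(g, slab$centroid_mm))
  ctr_lin <- as.integer(ctr_vox[1] + 30 * (ctr_vox[2] + 30 * ctr_vox[3]) + 1)
  expect_false(ctr_lin %in% gt1$voxel_idx)  # brute-force membership check
  mr <- match_lesions(list(gt1), list(slab))
  expect_false(mr$matches$detected[1])
  expect_equal(mr$fp_count, 0L)
})

test_that("multiple predictions matching one lesion are united for DSC/AVD", {
  g <- image_grid(c(30, 30, 30), c(1, 1, 1))
  gt <- make_lesion(box_indices(g, c(2, 2, 2), c(9, 9, 9)), g, "G")
  # two predicted halves, each with centroid inside the ground truth
  p1 <- make_lesion(box_indices(g, c(2, 2, 2), c(9, 9, 5)), g, "P1")
  p2 <- make_lesion(box_indices(g, c(2, 2, 6), c(9, 9, 9)), g, "P2")
  mr <- match_lesions(list(gt), list(p1, p2))
  expect_true(mr$matches$detected[1])
  expect_equal(mr$matches$n_matched[1], 2L)
  expect_equal(mr$matches$dsc[1], 1)  # union reconstructs the lesion
  expect_equal(mr$matches$avd_mm[1], 0)
  expect_equal(mr$fp_count, 0L)
})

test_that("sensitivity filters by effective-diameter intervals", {
  m <- data.frame(
    detected = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    gt_diameter_mm = c(3, 4, 5, 6, 7.5, 8, 10, 12, 15, 20)
  )
  expect_equal(sensitivity(m), 80)
  expect_equal(sensitivity(m, c(5, 7.5)), 50)     # lesions at 5, 6
  expect_equal(sensitivity(m, c(7.5, 10)), 50)    # lesions at 7.5, 8
  expect_equal(sensitivity(m, c(10, Inf)), 100)
  expect_true(is.na(sensitivity(m, c(50, Inf))))  # empty filter: undefined
  m$detected <- TRUE
  expect_equal(sensitivity(m), 100)
})

test_that("cohort aggregation pools lesions, averages FP per case", {
  g <- image_grid(c(30, 30, 30), c(1, 1, 1))
  gt1 <- make_lesion(box_indices(g, c(2, 2, 2), c(7, 7, 7)), g, "G1")
  gt2 <- make_lesion(box_indices(g, c(15, 15, 15), c(20, 20, 20)), g, "G2")
  stray <- make_lesion(box_indices(g, c(24, 24, 24), c(26, 26, 26)), g, "S")

  perfect <- evaluate_case("A", rasterize_to_lv(g, list(gt1, gt2)),
                           rasterize_to_lv(g, list(gt1, gt2)))
  expect_equal(perfect$mean_dsc, 1)
  expect_equal(perfect$mean_avd_mm, 0)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$fp_count, 0L)

  # case B: 1 of 2 detected plus one FP
  partial <- evaluate_case("B", rasterize_to_lv(g, list(gt1, gt2)),
                           rasterize_to_lv(g, list(gt1, stray)))
  expect_equal(partial$n_detected, 1L)
  expect_equal(partial$fp_count, 1L)

  s <- aggregate_cohort(list(perfect, partial))
  expect_equal(s$mean_fp, 0.5)
  # pooled sensitivity (3/4) — not the mean of per-case sensitivities
  expect_equal(s$sensitivity, 75)

  # a fixture where pooling and case-averaging genuinely differ
  one <- evaluate_case("C", rasterize_to_lv(g, list(gt1)),
                       rasterize_to_lv(g, list(gt1)))
  s2 <- aggregate_cohort(list(partial, one))
  expect_equal(s2$sensitivity, 100 * 2 / 3)
  case_mean <- mean(c(partial$sensitivity, one$sensitivity))
  expect_false(isTRUE(all.equal(s2$sensitivity, case_mean)))
})

test_that("no FP is counted when every prediction overlaps ground truth", {
  g <- image_grid(c(30, 30, 30), c(1, 1, 1))
  gt <- make_lesion(box_indices(g, c(2, 2, 2), c(9, 9, 9)), g, "G")
  shifted <- make_lesion(box_indices(g, c(5, 5, 5), c(12, 12, 12)), g, "P")
  mr <- match_lesions(list(gt), list(shifted))
  expect_equal(mr$fp_count, 0L)
})

test_that("undefined cohort DSC stays undefined, not zero", {
  g <- image_grid(c(30, 30, 30), c(1, 1, 1))
  gt <- make_lesion(box_indices(g, c(2, 2, 2), c(7, 7, 7)), g, "G")
  none <- evaluate_case("A", rasterize_to_lv(g, list(gt)), label_volume(g))
  s <- aggregate_cohort(list(none))
  expect_true(is.na(s$mean_dsc))
  expect_true(is.na(s$mean_avd_mm))
  expect_equal(s$sensitivity, 0)
})
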