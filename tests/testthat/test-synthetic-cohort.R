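small_box <- list(spacing = c(1, 1, 1), extent_mm = c(110, 110, 110))

test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- simulation_config(seed = 21, patients = 3, grid = small_box)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$gt, c2$gt)
  expect_identical(c1$pred, c2$pred)
  expect_identical(c1$covariates, c2$covariates)

  d1 <- tempfile(); d2 <- tempfile()
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_cohort(simulation_config(seed = 5, patients = 1,
                                              grid = small_box)))
  expect_identical(runif(1), before)
})

test_that("perfect detection with zero noise reproduces ground truth", {
  cfg <- simulation_config(seed = 8, patients = 3, grid = small_box,
                           detection = list(model = "constant", p = 1),
                           noise = list(radial_sd_mm = 0,
                                        offset_mm = c(0, 0, 0)),
                           fp = list(rate = 0, meanlog = log(0.05),
                                     sdlog = 0.7, min_cc = 0.01, max_cc = 2))
  coh <- generate_cohort(cfg)
  for (pid in names(coh$gt)) {
    gt_lv <- rasterize(coh$gt[[pid]], coh$grid)
    pred_lv <- rasterize(coh$pred[[pid]], coh$grid)
    expect_identical(gt_lv$voxels, pred_lv$voxels)
  }
  cases <- evaluate_cohort(coh)
  s <- aggregate_cohort(cases)
  expect_equal(s$mean_dsc, 1)
  expect_equal(s$mean_avd_mm, 0)
  expect_equal(s$sensitivity, 100)
  expect_equal(s$mean_fp, 0)
})

test_that("zero detection probability yields empty predictions", {
  cfg <- simulation_config(seed = 8, patients = 3, grid = small_box,
                           detection = list(model = "constant", p = 0),
                           fp = list(rate = 0, meanlog = log(0.05),
                                     sdlog = 0.7, min_cc = 0.01, max_cc = 2))
  coh <- generate_cohort(cfg)
  expect_true(all(vapply(coh$pred, function(s) length(s$structures),
                         integer(1)) == 0L))
})

test_that("default calibration reproduces the cohort medians", {
  all_counts <- integer(0)
  for (seed in c(1, 2, 3)) {
    cfg <- simulation_config(seed = seed, patients = 100)
    fr <- simulate_cohort_frame(cfg)
    all_counts <- c(all_counts, fr$patients$tumor_count)
    vols <- fr$lesions$size_cc
    # bootstrap CI of the sample median must cover the target 0.112 c.c.
    boots <- vapply(1:400, function(b)
      median(sample(vols, replace = TRUE)), numeric(1))
    ci <- quantile(boots, c(0.025, 0.975))
    expect_gte(0.112, ci[[1]])
    expect_lte(0.112, ci[[2]])
    expect_gte(min(vols), 0.010)
    expect_lte(max(vols), 26.475)
  }
  # the count distribution's median is 2 (a single 100-patient cohort's
  # sample median can sit at the 2/3 boundary, as in the emulated cohort)
  expect_equal(median(all_counts), 2)
  expect_gt(mean(all_counts <= 2), 0.5)
  expect_lt(mean(all_counts <= 1), 0.5)
})

test_that("increasing boundary noise degrades DSC and inflates AVD", {
  res <- lapply(c(0.3, 0.8, 1.4), function(sdn) {
    cfg <- simulation_config(seed = 14, patients = 8, grid = small_box,
                             detection = list(model = "constant", p = 1),
                             noise = list(radial_sd_mm = sdn,
                                          offset_mm = c(0, 0, 0)))
    aggregate_cohort(evaluate_cohort(generate_cohort(cfg)))
  })
  dscs <- vapply(res, `[[`, numeric(1), "mean_dsc")
  avds <- vapply(res, `[[`, numeric(1), "mean_avd_mm")
  expect_true(all(diff(dscs) < 0))
  expect_true(all(diff(avds) > 0))
})

test_that("lesions are placed with the configured separation", {
  cfg <- simulation_config(seed = 4, patients = 6, grid = small_box)
  coh <- generate_cohort(cfg)
  for (pid in unique(coh$truth$lesions$patient_id)) {
    tr <- coh$truth$lesions[coh$truth$lesions$patient_id == pid, ]
    if (nrow(tr) < 2) next
    ctr <- as.matrix(tr[, c("cx", "cy", "cz")])
    r <- tr$diameter_mm / 2
    dmat <- as.matrix(dist(ctr))
    need <- outer(r, r, `+`) + cfg$min_separation_mm
    off_diag <- upper.tri(dmat)
    expect_true(all(dmat[off_diag] >= need[off_diag] - 1e-9))
  }
})

test_that("parameter recovery flags truth/output identifier mismatches", {
  cfg <- simulation_config(seed = 6, patients = 2, grid = small_box)
  coh <- generate_cohort(cfg)
  s <- aggregate_cohort(evaluate_cohort(coh))
  expect_s3_class(recover_parameters(coh$truth, s), "data.frame")
  other <- generate_cohort(simulation_config(seed = 6, patients = 3,
                                             grid = small_box))
  expect_error(recover_parameters(other$truth, s), "different patients")
})

test_that("covariate effects shift detection only in the named stratum", {
  base <- simulation_config(seed = 40, patients = 300,
                            detection = list(model = "constant", p = 0.9))
  eff <- simulation_config(seed = 40, patients = 300,
                           detection = list(model = "constant", p = 0.9),
                           covariate_effects = list(
                             list(characteristic = "sex", level = "Male",
                                  detection_shift = -2.5)))
  fr0 <- simulate_cohort_frame(base)
  fr1 <- simulate_cohort_frame(eff)
  sens_by_sex <- function(fr) {
    agg <- merge(fr$lesions, fr$patients[, c("patient_id", "sex")])
    tapply(agg$detected, agg$sex, mean)
  }
  s0 <- sens_by_sex(fr0); s1 <- sens_by_sex(fr1)
  expect_lt(abs(s0[["Male"]] - s0[["Female"]]), 0.08)
  expect_lt(s1[["Male"]], s1[["Female"]] - 0.15)
})
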