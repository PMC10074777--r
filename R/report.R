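#' Configure an evaluation run
#'
#' A run either evaluates a directory tree of paired cases —
#' `gt_dir/<patient>.json` and `pred_dir/<patient>.json` (json-contours; or
#' `.nii` label volumes), paired by file base name, with a `covariates`
#' table and a reference `grid` — or simulates a cohort first
#' (`simulate = simulation_config(...)`) and evaluates it.
#'
#' @param gt_dir,pred_dir Input directories of per-patient structure files
#'   (ignored when `simulate` is given).
#' @param covariates Path to a covariate table, or a data frame.
#' @param grid An [image_grid()], or path to a `grid.json` written by
#'   [generate_cohort()].
#' @param simulate Optional [simulation_config()].
#' @param out_dir Output directory for the report bundle.
#' @param dialect Structure-set dialect for reading (`"json-contours"`,
#'   `"dicom-rtss"`, or `"nifti"` for label volumes).
#' @param thresholds Strictly increasing positive diameter thresholds (mm).
#' @param avd_variant Passed to [avd()].
#' @param age_scheme,size_scheme Grouping schemes for the stratified grid.
#' @param alpha Flagging threshold for the p-value grid.
#' @param seed Seed recorded in the manifest (the simulation seed when
#'   simulating).
#' @return An object of class `run_config`.
#' @export
run_config <- function(gt_dir = NULL, pred_dir = NULL, covariates = NULL,
                       grid = NULL, simulate = NULL, out_dir = NULL,
                       dialect = c("json-contours", "dicom-rtss", "nifti"),
                       thresholds = c(5, 7.5, 10),
                       avd_variant = c("symmetric", "max_directed"),
                       age_scheme = "tertiles", size_scheme = "quartiles",
                       alpha = 0.05, seed = NULL) {
  dialect <- match.arg(dialect)
  avd_variant <- match.arg(avd_variant)
  if (any(thresholds <= 0) || any(diff(thresholds) <= 0))
    stop("`thresholds` must be strictly increasing and positive",
         call. = FALSE)
  if (is.null(simulate) && (is.null(gt_dir) || is.null(pred_dir)))
    stop("either `simulate` or both `gt_dir` and `pred_dir` are required",
         call. = FALSE)
  structure(
    list(gt_dir = gt_dir, pred_dir = pred_dir, covariates = covariates,
         grid = grid, simulate = simulate, out_dir = out_dir,
         dialect = dialect, thresholds = thresholds,
         avd_variant = avd_variant, age_scheme = age_scheme,
         size_scheme = size_scheme, alpha = alpha,
         seed = seed %||% (if (!is.null(simulate)) simulate$seed)),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' All [run_config()] fields are accepted; a `simulate:` block is passed to
#' [simulation_config()].
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$simulate))
    doc$simulate <- do.call(simulation_config, doc$simulate)
  if (!is.null(doc$grid) && is.list(doc$grid))
    doc$grid <- do.call(image_grid, doc$grid)
  do.call(run_config, doc)
}

read_case_file <- function(path, dialect, grid) {
  if (dialect == "nifti") {
    lv <- read_label_volume(path)
    if (!is.null(grid) && !grids_equal(grid, lv$grid))
      stop(sprintf("grid of '%s' differs from the reference grid", path),
           call. = FALSE)
    lv
  } else {
    ss <- read_structure_set(path, dialect)
    rasterize(ss, grid)
  }
}

#' Evaluate all cases of a cohort
#'
#' Rasterizes each patient's ground-truth and predicted structure sets onto
#' the reference grid and runs [evaluate_case()].
#'
#' @param cohort A [generate_cohort()] result, or a list with named `gt`
#'   and `pred` lists of [structure_set()]s plus a `grid`.
#' @param avd_variant Passed to [avd()].
#' @param progress Print a dot every 10 cases.
#' @return List of `case_result`s, one per patient.
#' @export
evaluate_cohort <- function(cohort, avd_variant = "symmetric",
                            progress = FALSE) {
  ids <- names(cohort$gt)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    pid <- ids[i]
    gt_lv <- rasterize(cohort$gt[[pid]], cohort$grid)
    pred_lv <- rasterize(cohort$pred[[pid]], cohort$grid)
    out[[i]] <- evaluate_case(pid, gt_lv, pred_lv,
                              avd_variant = avd_variant)
    if (progress && i %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  stats::setNames(out, ids)
}

#' Run a full evaluation and write the report bundle
#'
#' Orchestrates the pipeline: obtain cases (simulate, or read and pair by
#' patient id, skipping unmatched cases with a warning), rasterize,
#' evaluate, aggregate, join covariates and run the stratified grid. The
#' bundle written to `out_dir` contains `per_lesion.csv`, `per_case.csv`,
#' `cohort_summary.json`, `sensitivity_bins.csv`, `stratified_grid.csv`
#' and `manifest.json` (config hash, package version, seed — no
#' timestamps, so a rerun with the same config and seed reproduces the
#' bundle byte for byte).
#'
#' @param config A [run_config()].
#' @return The report bundle (list), invisibly when written to disk.
#' @export
run_evaluation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    covariates <- cohort$covariates
    truth <- cohort$truth
  } else {
    grid <- config$grid
    if (is.character(grid)) grid <- read_grid_json(grid)
    ext <- if (config$dialect == "nifti") "\\.nii(\\.gz)?$" else "\\.(json|dcm)$"
    gt_files <- sort(list.files(config$gt_dir, ext, full.names = TRUE))
    pred_files <- sort(list.files(config$pred_dir, ext, full.names = TRUE))
    if (length(gt_files) == 0L)
      stop("no ground-truth cases found", call. = FALSE)
    strip <- function(f) sub("\\.(json|dcm|nii(\\.gz)?)$", "", basename(f))
    gt_ids <- strip(gt_files)
    pred_ids <- strip(pred_files)
    common <- intersect(gt_ids, pred_ids)
    orphans <- setdiff(union(gt_ids, pred_ids), common)
    if (length(orphans))
      warning(sprintf("unpaired case(s) skipped: %s",
                      paste(sort(orphans), collapse = ", ")))
    if (length(common) == 0L)
      stop("no paired ground-truth/predicted cases", call. = FALSE)
    dialect <- if (config$dialect == "nifti") "nifti" else config$dialect
    cohort <- list(
      grid = grid,
      gt = stats::setNames(lapply(gt_files[match(common, gt_ids)],
                                  read_case_file, dialect, grid), common),
      pred = stats::setNames(lapply(pred_files[match(common, pred_ids)],
                                    read_case_file, dialect, grid), common)
    )
    covariates <- config$covariates
    if (is.character(covariates)) covariates <- read_covariates(covariates)
    truth <- NULL
  }
  cases <- if (!is.null(config$simulate)) {
    evaluate_cohort(cohort, avd_variant = config$avd_variant)
  } else {
    # inputs may be pre-rasterized label volumes here
    stats::setNames(lapply(names(cohort$gt), function(pid) {
      gt <- cohort$gt[[pid]]
      pred <- cohort$pred[[pid]]
      if (inherits(gt, "structure_set")) gt <- rasterize(gt, cohort$grid)
      if (inherits(pred, "structure_set")) pred <- rasterize(pred, cohort$grid)
      evaluate_case(pid, gt, pred, avd_variant = config$avd_variant)
    }), names(cohort$gt))
  }
  summary <- aggregate_cohort(cases, thresholds = config$thresholds)
  frame <- NULL
  grid4 <- NULL
  if (!is.null(covariates)) {
    frame <- cohort_frame(cases, covariates)
    grid4 <- build_stratified_grid(frame, alpha = config$alpha,
                          age_scheme = config$age_scheme,
                          size_scheme = config$size_scheme,
                          on_error = "na")
  } else {
    warning("no covariate table: stratified grid skipped")
  }
  bundle <- list(config = config, cases = cases, summary = summary,
                 frame = frame, stratified = grid4, truth = truth)
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
    return(invisible(bundle))
  }
  bundle
}

config_for_manifest <- function(config) {
  cf <- unclass(config)
  cf$out_dir <- NULL
  if (!is.null(cf$simulate)) cf$simulate <- unclass(cf$simulate)
  if (inherits(cf$grid, "image_grid")) cf$grid <- unclass(cf$grid)
  if (is.data.frame(cf$covariates)) cf$covariates <- "<inline data frame>"
  cf
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(x) ifelse(is.na(x), NA, sprintf("%.10g", x))
  per_lesion <- bundle$summary$pooled
  for (col in c("dsc", "avd_mm", "avd_pct", "gt_volume_cc",
                "gt_diameter_mm"))
    per_lesion[[col]] <- num(per_lesion[[col]])
  write.csv(per_lesion, file.path(out_dir, "per_lesion.csv"),
            row.names = FALSE, quote = FALSE, na = "")
  per_case <- do.call(rbind, lapply(bundle$cases, function(cs) {
    data.frame(patient_id = cs$patient_id, n_gt = cs$n_gt,
               n_pred = cs$n_pred, n_detected = cs$n_detected,
               fp_count = cs$fp_count,
               sensitivity = num(cs$sensitivity),
               mean_dsc = num(cs$mean_dsc),
               mean_avd_mm = num(cs$mean_avd_mm),
               mean_avd_pct = num(cs$mean_avd_pct),
               stringsAsFactors = FALSE)
  }))
  write.csv(per_case, file.path(out_dir, "per_case.csv"),
            row.names = FALSE, quote = FALSE, na = "")
  s <- bundle$summary
  jsonlite::write_json(
    list(n_cases = s$n_cases, n_gt = s$n_gt, n_detected = s$n_detected,
         mean_dsc = s$mean_dsc, mean_avd_mm = s$mean_avd_mm,
         mean_avd_pct = s$mean_avd_pct, mean_fp = s$mean_fp,
         sensitivity = s$sensitivity,
         sensitivity_count_le2 = s$sensitivity_count_le2,
         sensitivity_count_ge3 = s$sensitivity_count_ge3,
         cumulative = s$cumulative),
    file.path(out_dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  bins <- s$bins
  bins$sensitivity <- num(bins$sensitivity)
  write.csv(bins, file.path(out_dir, "sensitivity_bins.csv"),
            row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(bundle$stratified)) {
    g <- as.data.frame(bundle$stratified)
    g$H <- num(g$H)
    g$p <- num(g$p)
    write.csv(g, file.path(out_dir, "stratified_grid.csv"),
              row.names = FALSE, quote = FALSE, na = "")
  }
  cfg_json <- jsonlite::toJSON(config_for_manifest(bundle$config),
                               auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- file.path(out_dir, "config.json")
  writeLines(cfg_json, tmp)
  manifest <- list(
    config_md5 = unname(tools::md5sum(tmp)),
    package = "lesionwise",
    package_version = as.character(utils::packageVersion("lesionwise")),
    seed = bundle$config$seed
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

fmt_or_na <- function(x, fmt) {
  if (is.null(x) || length(x) == 0L || is.na(x)) "n/a" else sprintf(fmt, x)
}

#' Render the report tables as text
#'
#' Produces three human-readable tables from a [run_evaluation()] bundle:
#' overall performance metrics, lesion-wise sensitivity by effective-
#' diameter bin, and the characteristic-by-metric p-value grid (with the
#' structurally absent size-by-FP cell marked). DSC is rendered at 3
#' decimals, percentages at 2, millimetres at 3; undefined values render
#' as `n/a`.
#'
#' @param bundle A [run_evaluation()] result.
#' @return Named character vector of table texts (`overall`, `by_diameter`,
#'   `stratified`); printed with [cat()].
#' @export
render_tables <- function(bundle) {
  s <- bundle$summary
  t2 <- c(
    "Performance metrics",
    "--------------------------------------------",
    sprintf("Mean lesion-wise DSC            %s", fmt_or_na(s$mean_dsc, "%.3f")),
    sprintf("Mean lesion-wise AVD            %s%% (%s mm)",
            fmt_or_na(s$mean_avd_pct, "%.2f"),
            fmt_or_na(s$mean_avd_mm, "%.3f")),
    sprintf("Mean FP count                   %.2f", s$mean_fp),
    sprintf("Lesion-wise sensitivity         %s%%",
            fmt_or_na(s$sensitivity, "%.2f")),
    sprintf("  diameter >= %g mm             %s%%",
            s$cumulative$threshold_mm[1],
            fmt_or_na(s$cumulative$sensitivity[1], "%.2f")),
    sprintf("  tumor count <= 2              %s%%",
            fmt_or_na(s$sensitivity_count_le2, "%.2f")),
    sprintf("  tumor count >= 3              %s%%",
            fmt_or_na(s$sensitivity_count_ge3, "%.2f"))
  )
  t3 <- c(
    "Lesion-wise sensitivity by effective diameter",
    "---------------------------------------------",
    vapply(seq_len(nrow(s$bins)), function(b) {
      sprintf("%-22s %s%%  (%d/%d)", s$bins$label[b],
              fmt_or_na(s$bins$sensitivity[b], "%.2f"),
              s$bins$n_detected[b], s$bins$n[b])
    }, character(1))
  )
  t4 <- if (is.null(bundle$stratified)) {
    c("Stratified grid", "---------------",
      "not available: no covariate table was supplied")
  } else {
    g <- bundle$stratified
    alpha <- attr(g, "alpha")
    c(sprintf(
        "Kruskal-Wallis p-values by characteristic and metric (* p < %g)",
        alpha),
      "----------------------------------------------------------------",
      vapply(seq_len(nrow(g)), function(i) {
        p_txt <- if (g$absent[i]) {
          "not assessable (no ground-truth size for false positives)"
        } else if (is.na(g$p[i])) {
          sprintf("n/a (%s)", g$note[i])
        } else {
          sprintf("%.3g%s", g$p[i], ifelse(g$flagged[i], " *", ""))
        }
        sprintf("%-8s %-13s x %-11s %s", g$level[i], g$characteristic[i],
                g$metric[i], p_txt)
      }, character(1)))
  }
  c(overall = paste(t2, collapse = "\n"),
    by_diameter = paste(t3, collapse = "\n"),
    stratified = paste(t4, collapse = "\n"))
}
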