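#' Dice similarity coefficient
#'
#' `2 * |A intersect B| / (|A| + |B|)` on voxel sets. Lesion-wise DSC is
#' computed between a ground-truth lesion and the union of the predicted
#' lesions matched to it.
#'
#' @param gt,pred Lesion objects or integer vectors of linear voxel indices
#'   on a common grid.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(gt, pred) {
  a <- if (inherits(gt, "lesion")) gt$voxel_idx else as.integer(gt)
  b <- if (inherits(pred, "lesion")) pred$voxel_idx else as.integer(pred)
  if (length(a) == 0L && length(b) == 0L)
    stop("DSC is undefined when both masks are empty", call. = FALSE)
  2 * sum(a %in% b) / (length(a) + length(b))
}

#' Average Hausdorff distance between a lesion and its prediction
#'
#' The average (symmetric) surface distance: the mean of the two directed
#' nearest-neighbor distance lists between the surface voxel centers of the
#' ground-truth lesion and of the (union of) matched predicted lesion(s).
#' Also returned relative to lesion size, as a percentage of the
#' ground-truth lesion's effective diameter.
#'
#' @param gt Ground-truth lesion.
#' @param pred Predicted lesion (union of matched components).
#' @param grid Optional grid consistency check.
#' @param variant `"symmetric"` (default): mean of the concatenated directed
#'   lists; `"max_directed"`: maximum of the two directed means.
#' @return `list(avd_mm = ..., avd_pct = ...)`.
#' @export
avd <- function(gt, pred, grid = NULL,
                variant = c("symmetric", "max_directed")) {
  variant <- match.arg(variant)
  sd2 <- surface_distances(gt, pred, grid)
  avd_mm <- if (variant == "symmetric") {
    mean(c(sd2$a_to_b, sd2$b_to_a))
  } else {
    max(mean(sd2$a_to_b), mean(sd2$b_to_a))
  }
  list(avd_mm = avd_mm,
       avd_pct = 100 * avd_mm / gt$effective_diameter_mm)
}

#' Match predicted lesions to ground-truth lesions
#'
#' Implements the detection criterion and the false-positive rule:
#' * a ground-truth lesion is **detected** iff the physical centroid of at
#'   least one predicted lesion, mapped to its nearest voxel, is a member
#'   voxel of that ground-truth lesion;
#' * a predicted lesion is a **false positive** iff it shares no voxel with
#'   the union of all ground-truth lesions.
#'
#' The two rules are deliberately asymmetric: a prediction that overlaps a
#' ground-truth lesion without placing its centroid inside it produces
#' neither a detection nor a false positive. When several predicted
#' components place their centroids inside one ground-truth lesion, their
#' union is used as the prediction for DSC/AVD.
#'
#' @param gt,pred Lists of lesion objects (from [connected_components()])
#'   on one common grid.
#' @param grid Optional reference grid; defaults to the lesions' grid.
#' @param avd_variant Passed to [avd()].
#' @return An object of class `match_result`: a list with `matches` (one
#'   data-frame row per ground-truth lesion: `gt_id`, `detected`, `dsc`,
#'   `avd_mm`, `avd_pct`, `gt_volume_cc`, `gt_diameter_mm`, `n_matched`),
#'   `matched_ids` (list of predicted ids per ground-truth lesion),
#'   `fp_count`, `fp_ids` and `n_pred`.
#' @export
match_lesions <- function(gt, pred, grid = NULL,
                          avd_variant = c("symmetric", "max_directed")) {
  avd_variant <- match.arg(avd_variant)
  all_lesions <- c(gt, pred)
  if (length(all_lesions) > 0L) {
    g0 <- if (!is.null(grid)) grid else all_lesions[[1]]$grid
    for (l in all_lesions)
      if (!grids_equal(l$grid, g0))
        stop("ground-truth and predicted lesions must share one grid",
             call. = FALSE)
  } else {
    g0 <- grid
  }

  gt_union <- unlist(lapply(gt, `[[`, "voxel_idx"), use.names = FALSE)

  # Nearest voxel of each predicted centroid, as a linear index.
  pred_centroid_idx <- vapply(pred, function(p) {
    ijk <- round(physical_to_voxel(p$grid, p$centroid_mm))
    ijk <- pmin(pmax(ijk, 0), matrix(p$grid$shape - 1L, 1)) # clamp to grid
    ijk_to_idx(ijk, p$grid$shape)
  }, integer(1))

  fp <- vapply(pred, function(p) !any(p$voxel_idx %in% gt_union), logical(1))

  matched_ids <- vector("list", length(gt))
  rows <- vector("list", length(gt))
  for (i in seq_along(gt)) {
    g <- gt[[i]]
    hit <- which(pred_centroid_idx %in% g$voxel_idx)
    detected <- length(hit) > 0L
    d <- a_mm <- a_pct <- NA_real_
    if (detected) {
      union_idx <- unique(unlist(lapply(pred[hit], `[[`, "voxel_idx")))
      pu <- lesion_from_indices(union_idx, g$grid, "pred_union")
      d <- dsc(g, pu)
      av <- avd(g, pu, variant = avd_variant)
      a_mm <- av$avd_mm
      a_pct <- av$avd_pct
      matched_ids[[i]] <- vapply(pred[hit], `[[`, character(1), "id")
    } else {
      matched_ids[[i]] <- character(0)
    }
    rows[[i]] <- data.frame(
      gt_id = g$id, detected = detected, dsc = d,
      avd_mm = a_mm, avd_pct = a_pct,
      gt_volume_cc = g$volume_cc,
      gt_diameter_mm = g$effective_diameter_mm,
      n_matched = length(matched_ids[[i]]),
      stringsAsFactors = FALSE
    )
  }
  matches <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gt_id = character(0), detected = logical(0), dsc = numeric(0),
    avd_mm = numeric(0), avd_pct = numeric(0), gt_volume_cc = numeric(0),
    gt_diameter_mm = numeric(0), n_matched = integer(0),
    stringsAsFactors = FALSE
  )
  structure(
    list(matches = matches, matched_ids = matched_ids,
         fp_count = sum(fp),
         fp_ids = vapply(pred[fp], `[[`, character(1), "id"),
         n_pred = length(pred)),
    class = "match_result"
  )
}

#' Lesion-wise sensitivity
#'
#' Detected ground-truth lesions divided by all ground-truth lesions, as a
#' percentage, optionally restricted to lesions whose effective diameter
#' falls in a half-open interval `[lo, hi)` (use `hi = Inf` for the
#' cumulative ">= threshold" filters).
#'
#' @param matches A `match_result` or its `matches` data frame.
#' @param diameter_range Optional `c(lo, hi)` in mm; lesions with
#'   `lo <= diameter < hi` are kept.
#' @return Sensitivity in percent, or `NA_real_` if no lesion passes the
#'   filter (undefined, never a division by zero).
#' @export
sensitivity <- function(matches, diameter_range = NULL) {
  m <- if (inherits(matches, "match_result")) matches$matches else matches
  keep <- rep(TRUE, nrow(m))
  if (!is.null(diameter_range)) {
    stopifnot(length(diameter_range) == 2L, diameter_range[1] < diameter_range[2])
    keep <- m$gt_diameter_mm >= diameter_range[1] &
      m$gt_diameter_mm < diameter_range[2]
  }
  if (!any(keep)) return(NA_real_)
  100 * sum(m$detected[keep]) / sum(keep)
}

#' Evaluate one patient case
#'
#' Runs component extraction (if needed), detection matching and the
#' lesion-wise metrics for one ground-truth / predicted pair, and computes
#' the per-case aggregates: per-case means of DSC and AVD are taken over
#' detected lesions only.
#'
#' @param patient_id Patient identifier.
#' @param gt,pred [label_volume()]s (or lists of lesion objects) on one
#'   common reference grid.
#' @param avd_variant Passed to [avd()].
#' @return An object of class `case_result`.
#' @export
evaluate_case <- function(patient_id, gt, pred,
                          avd_variant = c("symmetric", "max_directed")) {
  avd_variant <- match.arg(avd_variant)
  if (inherits(gt, "label_volume")) gt <- connected_components(gt)
  if (inherits(pred, "label_volume")) pred <- connected_components(pred)
  mr <- match_lesions(gt, pred, avd_variant = avd_variant)
  m <- mr$matches
  det <- m$detected
  structure(
    list(patient_id = as.character(patient_id),
         matches = m,
         fp_count = mr$fp_count,
         n_gt = nrow(m),
         n_pred = mr$n_pred,
         n_detected = sum(det),
         sensitivity = sensitivity(mr),
         mean_dsc = if (any(det)) mean(m$dsc[det]) else NA_real_,
         mean_avd_mm = if (any(det)) mean(m$avd_mm[det]) else NA_real_,
         mean_avd_pct = if (any(det)) mean(m$avd_pct[det]) else NA_real_),
    class = "case_result"
  )
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf(
    "<case_result %s> %d/%d lesions detected (%.1f%%), FP %d, mean DSC %s\n",
    x$patient_id, x$n_detected, x$n_gt,
    if (is.na(x$sensitivity)) NA else x$sensitivity, x$fp_count,
    ifelse(is.na(x$mean_dsc), "n/a", sprintf("%.3f", x$mean_dsc))))
  invisible(x)
}

#' Aggregate case results over a cohort
#'
#' Cohort-level metrics follow the study conventions: mean lesion-wise DSC
#' and AVD are pooled over *all detected lesions* across the cohort (not
#' averaged per case first); mean FP count is the mean of the per-case
#' counts; lesion-wise sensitivity is pooled over all ground-truth lesions,
#' overall, cumulatively above each diameter threshold, per half-open
#' diameter bin, and split by per-patient tumor count (<= 2 vs >= 3).
#'
#' @param cases List of [evaluate_case()] results.
#' @param thresholds Increasing positive diameter thresholds in mm
#'   (default 5, 7.5, 10).
#' @return An object of class `cohort_summary`.
#' @export
aggregate_cohort <- function(cases, thresholds = c(5, 7.5, 10)) {
  stopifnot(length(cases) >= 1L)
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0))
    stop("`thresholds` must be strictly increasing and positive",
         call. = FALSE)
  pooled <- do.call(rbind, lapply(cases, function(cs) {
    cbind(patient_id = cs$patient_id, cs$matches,
          stringsAsFactors = FALSE)
  }))
  det <- pooled$detected
  n_gt <- nrow(pooled)
  edges <- c(thresholds, Inf)
  bins <- data.frame(
    lo = thresholds,
    hi = edges[-1],
    label = c(sprintf("[%g, %g) mm", thresholds[-length(thresholds)],
                      thresholds[-1]),
              sprintf(">= %g mm", thresholds[length(thresholds)])),
    stringsAsFactors = FALSE
  )
  bins$n <- bins$n_detected <- 0L
  bins$sensitivity <- NA_real_
  for (b in seq_len(nrow(bins))) {
    keep <- pooled$gt_diameter_mm >= bins$lo[b] &
      pooled$gt_diameter_mm < bins$hi[b]
    bins$n[b] <- sum(keep)
    bins$n_detected[b] <- sum(det[keep])
    bins$sensitivity[b] <- if (any(keep)) 100 * sum(det[keep]) / sum(keep)
                           else NA_real_
  }
  cumulative <- data.frame(
    threshold_mm = thresholds,
    sensitivity = vapply(thresholds, function(t) {
      keep <- pooled$gt_diameter_mm >= t
      if (any(keep)) 100 * sum(det[keep]) / sum(keep) else NA_real_
    }, numeric(1))
  )
  count_group <- vapply(cases, function(cs) cs$n_gt, integer(1))
  sens_by_count <- function(sel) {
    ids <- vapply(cases[sel], `[[`, character(1), "patient_id")
    keep <- pooled$patient_id %in% ids
    if (any(keep)) 100 * sum(det[keep]) / sum(keep) else NA_real_
  }
  structure(
    list(n_cases = length(cases),
         n_gt = n_gt,
         n_detected = sum(det),
         mean_dsc = if (any(det)) mean(pooled$dsc[det]) else NA_real_,
         mean_avd_mm = if (any(det)) mean(pooled$avd_mm[det]) else NA_real_,
         mean_avd_pct = if (any(det)) mean(pooled$avd_pct[det]) else NA_real_,
         mean_fp = mean(vapply(cases, `[[`, numeric(1), "fp_count")),
         sensitivity = if (n_gt > 0) 100 * sum(det) / n_gt else NA_real_,
         sensitivity_count_le2 = sens_by_count(count_group <= 2),
         sensitivity_count_ge3 = sens_by_count(count_group >= 3),
         cumulative = cumulative,
         bins = bins,
         pooled = pooled),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(v, f) ifelse(is.na(v), "n/a", sprintf(f, v))
  cat(sprintf("<cohort_summary> %d cases, %d ground-truth lesions\n",
              x$n_cases, x$n_gt))
  cat(sprintf("  mean lesion-wise DSC  %s\n", fmt(x$mean_dsc, "%.3f")))
  cat(sprintf("  mean lesion-wise AVD  %s%% (%s mm)\n",
              fmt(x$mean_avd_pct, "%.2f"), fmt(x$mean_avd_mm, "%.3f")))
  cat(sprintf("  mean FP count         %.2f\n", x$mean_fp))
  cat(sprintf("  lesion-wise sensitivity %s%%\n",
              fmt(x$sensitivity, "%.2f")))
  invisible(x)
}
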