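#' Read a patient covariate table
#'
#' Delimited text (tab or comma separated, sniffed from the header line)
#' with at least the columns `patient_id`, `sex`, `age`, `race`,
#' `histology`; extra columns (e.g. `treatment_year`) are kept.
#'
#' @param path Path to the covariate file.
#' @return A data frame, one row per patient.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path))
    stop(sprintf("covariate file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  df <- if (grepl("\t", header)) read.delim(path, stringsAsFactors = FALSE)
        else read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "sex", "age", "race", "histology")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("covariate table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Write a covariate table
#'
#' @param covariates Data frame with a `patient_id` column.
#' @param path Output path (written tab-separated).
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Join per-case metrics to patient covariates
#'
#' Builds the analysis frame for the stratified tests: one record per
#' patient (covariates plus per-case metric aggregates, with per-patient
#' tumor count taken from the ground truth) and one record per
#' ground-truth lesion (size, detection indicator, DSC, AVD).
#'
#' @param cases List of [evaluate_case()] results.
#' @param covariates Data frame as from [read_covariates()]. Patients
#'   without a covariate row are dropped with a warning.
#' @return An object of class `cohort_frame`: `list(patients = ...,
#'   lesions = ...)`.
#' @export
cohort_frame <- function(cases, covariates) {
  ids <- vapply(cases, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids))
    stop("duplicate patient ids in `cases`", call. = FALSE)
  keep <- ids %in% covariates$patient_id
  if (!all(keep)) {
    warning(sprintf("%d case(s) without covariates dropped: %s",
                    sum(!keep), paste(ids[!keep], collapse = ", ")))
    cases <- cases[keep]
    ids <- ids[keep]
  }
  if (length(cases) == 0L)
    stop("no case has a covariate record", call. = FALSE)
  per_case <- data.frame(
    patient_id = ids,
    tumor_count = vapply(cases, `[[`, integer(1), "n_gt"),
    mean_dsc = vapply(cases, `[[`, numeric(1), "mean_dsc"),
    mean_avd_mm = vapply(cases, `[[`, numeric(1), "mean_avd_mm"),
    mean_avd_pct = vapply(cases, `[[`, numeric(1), "mean_avd_pct"),
    fp_count = vapply(cases, function(x) as.numeric(x$fp_count), numeric(1)),
    sensitivity = vapply(cases, `[[`, numeric(1), "sensitivity"),
    stringsAsFactors = FALSE
  )
  patients <- merge(covariates, per_case, by = "patient_id", sort = TRUE)
  lesions <- do.call(rbind, lapply(cases, function(cs) {
    m <- cs$matches
    data.frame(patient_id = cs$patient_id,
               lesion_id = m$gt_id,
               size_cc = m$gt_volume_cc,
               diameter_mm = m$gt_diameter_mm,
               detected = as.integer(m$detected),
               dsc = m$dsc,
               avd_mm = m$avd_mm,
               avd_pct = m$avd_pct,
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(lesions$patient_id %in% patients$patient_id))
  structure(list(patients = patients, lesions = lesions),
            class = "cohort_frame")
}

#' @export
print.cohort_frame <- function(x, ...) {
  cat(sprintf("<cohort_frame> %d patients, %d ground-truth lesions\n",
              nrow(x$patients), nrow(x$lesions)))
  invisible(x)
}
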