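#' Kruskal-Wallis test on grouped observations
#'
#' Rank-based k-sample test: the H statistic is computed on midranks with
#' the tie-correction factor `1 - sum(t^3 - t) / (N^3 - N)` and referred to
#' a chi-square distribution with k - 1 degrees of freedom (this is what
#' `stats::kruskal.test` computes; it is called under the hood). Two
#' conventions are added for the degenerate cases this pipeline produces:
#' when all pooled observations are identical the test returns `(H = 0,
#' p = 1)`, and a Monte-Carlo permutation p-value is available for small
#' groups where the chi-square approximation is doubtful.
#'
#' @param groups List of >= 2 non-empty numeric vectors (>= 3 observations
#'   in total).
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations for `method = "permutation"`.
#' @return `list(H, df, p, group_sizes, method)`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))  # H = 3.857, p ~ 0.0495
#' @export
kruskal_wallis <- function(groups, method = c("chisq", "permutation"),
                           n_perm = 2000L) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes == 0L))
    stop("every group must be non-empty", call. = FALSE)
  x <- as.numeric(unlist(groups, use.names = FALSE))
  if (any(!is.finite(x)))
    stop("observations must be finite", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 observations in total", call. = FALSE)
  g <- factor(rep.int(seq_along(groups), sizes))
  out <- list(H = 0, df = length(groups) - 1L, p = 1,
              group_sizes = as.integer(sizes), method = method)
  if (all(x == x[1L])) return(out)  # all-ties convention: (0, 1)
  kt <- suppressWarnings(stats::kruskal.test(x, g))
  out$H <- unname(kt$statistic)
  out$p <- kt$p.value
  if (method == "permutation") {
    # Under label permutation the pooled midranks (and hence the tie
    # correction and the affine constants of H) are fixed, so H is a
    # monotone transform of S = sum_i (rank sum of group i)^2 / n_i;
    # comparing S suffices and needs no per-draw re-ranking.
    r <- rank(x)
    gi <- as.integer(g)
    n <- length(r)
    s_obs <- sum(rowsum(r, gi)^2 / sizes)
    # all draws at once: column-wise random orders, group-wise rank sums
    idx <- apply(matrix(runif(n * n_perm), n, n_perm), 2L, order)
    sums <- rowsum(matrix(r[idx], n, n_perm), gi)
    s_perm <- colSums(sums^2 / sizes)
    out$p <- (sum(s_perm >= s_obs - 1e-9) + 1L) / (n_perm + 1L)
  }
  out
}

# Grouping schemes -----------------------------------------------------------

#' @keywords internal
cut_numeric_groups <- function(values, scheme, what) {
  if (is.character(scheme)) {
    scheme <- match.arg(scheme, c("tertiles", "quartiles", "median"))
    probs <- switch(scheme,
                    tertiles = c(1 / 3, 2 / 3),
                    quartiles = c(0.25, 0.5, 0.75),
                    median = 0.5)
    cuts <- unique(quantile(values, probs, na.rm = TRUE, names = FALSE))
  } else {
    cuts <- sort(unique(as.numeric(scheme)))
  }
  if (length(cuts) == 0L)
    stop(sprintf("cannot group %s: degenerate cut points", what),
         call. = FALSE)
  cut(values, breaks = c(-Inf, cuts, Inf), right = FALSE)
}

tumor_count_groups <- function(counts, scheme = c(1, 2, 3, 4)) {
  # default bins 1 / 2 / 3 / 4 / >= 5, the cohort-table categories
  cuts <- sort(unique(as.numeric(scheme)))
  labels <- c(as.character(cuts), sprintf(">=%g", cuts[length(cuts)] + 1))
  cut(counts, breaks = c(cuts - 0.5, cuts[length(cuts)] + 0.5, Inf),
      labels = labels, right = TRUE)
}

#' Stratified Kruskal-Wallis test of one characteristic against one metric
#'
#' Assembles groups according to the characteristic's grouping scheme,
#' excludes records with undefined metric values (reporting the exclusion
#' count), drops empty groups, and applies [kruskal_wallis()].
#'
#' Patient-level characteristics: `sex`, `age` (tertiles by default),
#' `race`, `histology`, `tumor_count` (bins 1/2/3/4/>=5),
#' `treatment_year`. Patient-level metrics: `dsc`, `avd_mm`, `avd_pct`,
#' `fp_count`, `sensitivity` (the per-case aggregates).
#' Lesion-level characteristic: `size` (quartiles by default); lesion-level
#' metrics: `dsc`, `avd_mm`, `avd_pct`, `detected` (the binary detection
#' indicator, which aggregates to lesion-wise sensitivity).
#'
#' The lesion-size-versus-FP-count cell is *structurally absent*: a false
#' positive has no ground-truth size, so the test cannot be formed; the
#' returned object carries `absent = TRUE` instead of a p-value.
#'
#' @param frame A [cohort_frame()].
#' @param characteristic Characteristic name (see Details).
#' @param metric Metric name (see Details).
#' @param scheme Optional grouping scheme for `age`, `size`
#'   (`"tertiles"`, `"quartiles"`, `"median"`, or numeric cut points) or
#'   `tumor_count` (numeric bin values).
#' @param method,n_perm Passed to [kruskal_wallis()].
#' @param warn_small Warn when any group has fewer than 5 observations
#'   (chi-square approximation doubtful; consider
#'   `method = "permutation"`).
#' @return An object of class `stratified_test`.
#' @export
stratify <- function(frame, characteristic, metric, scheme = NULL,
                     method = c("chisq", "permutation"), n_perm = 2000L,
                     warn_small = TRUE) {
  stopifnot(inherits(frame, "cohort_frame"))
  method <- match.arg(method)
  patient_chars <- c("sex", "age", "race", "histology", "tumor_count",
                     "treatment_year")
  level <- if (characteristic %in% patient_chars) "patient"
           else if (characteristic == "size") "lesion"
           else stop(sprintf("unknown characteristic '%s'", characteristic),
                     call. = FALSE)

  base <- list(characteristic = characteristic, metric = metric,
               level = level)

  if (level == "lesion" && metric == "fp_count") {
    # no ground-truth size exists for a false positive
    return(structure(c(base, list(
      absent = TRUE,
      reason = "false positives have no ground-truth size")),
      class = "stratified_test"))
  }

  if (level == "patient") {
    df <- frame$patients
    col <- switch(metric,
                  dsc = "mean_dsc", avd_mm = "mean_avd_mm",
                  avd_pct = "mean_avd_pct", fp_count = "fp_count",
                  sensitivity = "sensitivity",
                  stop(sprintf("unknown patient-level metric '%s'", metric),
                       call. = FALSE))
    values <- df[[col]]
    grouping <- switch(characteristic,
      sex = , race = , histology = , treatment_year =
        factor(df[[characteristic]]),
      age = cut_numeric_groups(df$age, scheme %||% "tertiles", "age"),
      tumor_count = tumor_count_groups(df$tumor_count,
                                       scheme %||% c(1, 2, 3, 4)))
  } else {
    df <- frame$lesions
    col <- switch(metric,
                  dsc = "dsc", avd_mm = "avd_mm", avd_pct = "avd_pct",
                  detected = , sensitivity = "detected",
                  stop(sprintf("unknown lesion-level metric '%s'", metric),
                       call. = FALSE))
    values <- as.numeric(df[[col]])
    grouping <- cut_numeric_groups(df$size_cc, scheme %||% "quartiles",
                                   "lesion size")
  }

  ok <- !is.na(values) & !is.na(grouping)
  n_excluded <- sum(!ok)
  values <- values[ok]
  grouping <- droplevels(factor(grouping[ok]))
  if (length(values) == 0L)
    stop(sprintf(
      "all records excluded for %s x %s (no defined metric values)",
      characteristic, metric), call. = FALSE)
  groups <- split(values, grouping)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L)
    stop(sprintf("fewer than 2 non-empty groups for %s x %s",
                 characteristic, metric), call. = FALSE)
  if (warn_small && any(lengths(groups) < 5L))
    warning(sprintf(
      "%s x %s: group(s) with < 5 observations; chi-square approximation may be poor",
      characteristic, metric), call. = FALSE)
  kw <- kruskal_wallis(groups, method = method, n_perm = n_perm)
  structure(c(base, list(
    absent = FALSE,
    group_labels = names(groups),
    group_sizes = kw$group_sizes,
    H = kw$H, df = kw$df, p = kw$p,
    n_used = length(values), n_excluded = n_excluded,
    method = kw$method)),
    class = "stratified_test")
}

#' @export
print.stratified_test <- function(x, ...) {
  if (isTRUE(x$absent)) {
    cat(sprintf("<stratified_test> %s x %s: not assessable (%s)\n",
                x$characteristic, x$metric, x$reason))
  } else {
    cat(sprintf(
      "<stratified_test> %s x %s: H = %.3f, df = %d, p = %.3g (n = %d, excluded %d)\n",
      x$characteristic, x$metric, x$H, x$df, x$p, x$n_used, x$n_excluded))
  }
  invisible(x)
}

#' Full characteristic-by-metric Kruskal-Wallis grid
#'
#' Runs the whole stratified grid: five patient-level characteristics
#' (sex, age, race, histology, tumor count) against the four per-case
#' metrics (DSC, AVD in mm and %, FP count, sensitivity), plus the
#' lesion-level tumor-size tests against lesion-wise DSC, AVD and the
#' detection indicator. The size-by-FP cell is structurally absent. Cells
#' with p below `alpha` are flagged.
#'
#' @param frame A [cohort_frame()].
#' @param alpha Flagging threshold (default 0.05, applied per test).
#' @param age_scheme,size_scheme,count_scheme Grouping schemes (see
#'   [stratify()]).
#' @param p_adjust `"none"` (default, per-test threshold) or any
#'   [stats::p.adjust()] method such as `"holm"`.
#' @param method,n_perm Passed to [kruskal_wallis()].
#' @param warn_small Passed to [stratify()].
#' @param on_error `"stop"` (default) propagates errors from [stratify()]
#'   (e.g. all records excluded); `"na"` records the message in a `note`
#'   column and leaves the cell's p-value `NA` — the mode used by
#'   [run_evaluation()] so one degenerate cell cannot void a report.
#' @return An object of class `table_grid`: a data frame of test results
#'   with attributes `alpha` and `p_adjust`.
#' @export
build_stratified_grid <- function(frame, alpha = 0.05,
                         age_scheme = "tertiles", size_scheme = "quartiles",
                         count_scheme = c(1, 2, 3, 4),
                         p_adjust = "none",
                         method = c("chisq", "permutation"), n_perm = 2000L,
                         warn_small = FALSE, on_error = c("stop", "na")) {
  stopifnot(inherits(frame, "cohort_frame"))
  method <- match.arg(method)
  on_error <- match.arg(on_error)
  patient_chars <- c("sex", "age", "race", "histology", "tumor_count")
  metrics <- c("dsc", "avd_mm", "avd_pct", "fp_count", "sensitivity")
  cells <- rbind(
    expand.grid(characteristic = patient_chars, metric = metrics,
                stringsAsFactors = FALSE),
    expand.grid(characteristic = "size",
                metric = c("dsc", "avd_mm", "avd_pct", "fp_count",
                           "detected"),
                stringsAsFactors = FALSE)
  )
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ch <- cells$characteristic[i]
    me <- cells$metric[i]
    scheme <- switch(ch, age = age_scheme, size = size_scheme,
                     tumor_count = count_scheme, NULL)
    lvl <- if (ch == "size") "lesion" else "patient"
    st <- if (on_error == "stop") {
      stratify(frame, ch, me, scheme = scheme, method = method,
               n_perm = n_perm, warn_small = warn_small)
    } else {
      tryCatch(
        stratify(frame, ch, me, scheme = scheme, method = method,
                 n_perm = n_perm, warn_small = warn_small),
        error = function(e) conditionMessage(e))
    }
    if (is.character(st)) {
      data.frame(level = lvl, characteristic = ch, metric = me,
                 H = NA_real_, df = NA_integer_, p = NA_real_,
                 n_used = NA_integer_, n_excluded = NA_integer_,
                 absent = FALSE, note = st, stringsAsFactors = FALSE)
    } else if (isTRUE(st$absent)) {
      data.frame(level = st$level, characteristic = ch, metric = me,
                 H = NA_real_, df = NA_integer_, p = NA_real_,
                 n_used = NA_integer_, n_excluded = NA_integer_,
                 absent = TRUE, note = st$reason, stringsAsFactors = FALSE)
    } else {
      data.frame(level = st$level, characteristic = ch, metric = me,
                 H = st$H, df = st$df, p = st$p, n_used = st$n_used,
                 n_excluded = st$n_excluded, absent = FALSE, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  grid <- do.call(rbind, rows)
  if (p_adjust != "none")
    grid$p[!grid$absent] <- stats::p.adjust(grid$p[!grid$absent],
                                            method = p_adjust)
  grid$flagged <- !grid$absent & !is.na(grid$p) & grid$p < alpha
  structure(grid, class = c("table_grid", "data.frame"),
            alpha = alpha, p_adjust = p_adjust)
}
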