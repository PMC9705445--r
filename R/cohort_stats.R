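# Cohort statistics: group comparisons, change scores, subgroups,
# deterioration/improvement classification and the standard study reports.
#
# Comparisons follow the study's analysis plan: chi-square for sex,
# two-sided Mann-Whitney (Wilcoxon rank-sum) for everything else, medians
# with min-max ranges, change scores as follow-up minus initial, subgroup
# contrasts against controls without multiplicity correction, significance
# at p <= 0.05.

#' Median and range
#'
#' Sample median (midpoint of the two central order statistics for even n)
#' and extremes, ignoring missing values.
#'
#' @param values Numeric vector.
#' @return Named vector `c(median, min, max)`; all `NA` if no non-missing
#'   values.
#' @export
median_range <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values))
    return(c(median = NA_real_, min = NA_real_, max = NA_real_))
  c(median = median(values), min = min(values), max = max(values))
}

comparison_result <- function(variable, test, method, statistic, p,
                              n, summaries) {
  structure(list(variable = variable, test = test, method = method,
                 statistic = statistic, p = p, n = n,
                 summaries = summaries),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s (%s), statistic = %.4g, p = %.4g, n = %s\n",
              x$variable, x$test, x$method, x$statistic, x$p,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Two-sided Mann-Whitney test
#'
#' Compares two groups with the Wilcoxon rank-sum test. The exact null
#' distribution is used when both groups have at most 25 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used. The reported statistic is U for the first
#' group.
#'
#' @param a,b Numeric vectors (missing values dropped).
#' @param variable Label carried into the result.
#' @return A `comparison_result` with per-group median/range summaries.
#' @export
mann_whitney <- function(a, b, variable = "value") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups need at least one value")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= 25 && length(b) <= 25
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  comparison_result(variable, "Mann-Whitney",
                    if (exact) "exact"
                    else "normal approximation (tie/continuity corrected)",
                    statistic = unname(wt$statistic), p = wt$p.value,
                    n = c(length(a), length(b)),
                    summaries = list(a = median_range(a), b = median_range(b)))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1, two-sided (as used for the sex
#' comparison).
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @param variable Label carried into the result.
#' @return A `comparison_result`.
#' @export
chi_square_2x2 <- function(counts, variable = "counts") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the 2x2 table")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  comparison_result(variable, "chi-square", "Pearson, df = 1",
                    statistic = unname(ct$statistic), p = ct$p.value,
                    n = rowSums(counts), summaries = list(counts = counts))
}

#' Per-subject change scores
#'
#' Follow-up minus initial for every outcome (and any optional numeric
#' column such as pulmonary-function values) in a long outcomes table. A
#' positive change in a curvature outcome means increased diaphragmatic
#' curvature over time, i.e. deterioration. Missing visit values propagate
#' to missing changes.
#'
#' @param outcomes An `outcomes_table` (see
#'   [load_supplementary_outcomes()]).
#' @param variables Columns to difference; defaults to all numeric columns.
#' @return Data frame: one row per subject with `id`, `group` and one change
#'   column per variable.
#' @export
change_scores <- function(outcomes, variables = NULL) {
  stopifnot(is.data.frame(outcomes),
            all(c("id", "group", "visit") %in% names(outcomes)))
  if (is.null(variables))
    variables <- names(outcomes)[vapply(outcomes, is.numeric, TRUE) &
                                   !names(outcomes) %in% c("id")]
  ini <- outcomes[outcomes$visit == "initial", ]
  fol <- outcomes[outcomes$visit == "follow-up", ]
  ids <- unique(outcomes$id)
  out <- data.frame(id = ids,
                    group = ini$group[match(ids, ini$id)],
                    stringsAsFactors = FALSE)
  out$group[is.na(out$group)] <- fol$group[match(ids[is.na(out$group)],
                                                 fol$id)]
  for (v in variables)
    out[[v]] <- fol[[v]][match(ids, fol$id)] - ini[[v]][match(ids, ini$id)]
  out
}

#' Classify a curvature change
#'
#' Sign-based label for the change in diaphragm height ratio: positive
#' (increased curvature over time) is deterioration, negative is
#' improvement, exactly zero is labelled stable, missing is unclassified.
#'
#' @param height_ratio_change Numeric vector of change scores.
#' @return Character vector of labels.
#' @export
classify_change <- function(height_ratio_change) {
  ifelse(is.na(height_ratio_change), "unclassified",
         ifelse(height_ratio_change > 0, "deterioration",
                ifelse(height_ratio_change < 0, "improvement", "stable")))
}

#' Treatment-duration subgroup of a patient
#'
#' Partitions patients by enzyme-replacement-therapy exposure at the initial
#' MRI: untreated, treated for at most 3 years (boundary closed at 3.0;
#' negative durations, i.e. treatment started between the visits, stay in
#' this group), or treated for more than 3 years.
#'
#' @param ert_status Character vector, `"untreated"`/`"treated"` (`NA` for
#'   controls).
#' @param ert_duration_years Numeric vector: years of therapy at the initial
#'   MRI.
#' @return Factor with levels `untreated`, `le3y`, `gt3y` (`NA` for
#'   controls).
#' @export
ert_group <- function(ert_status, ert_duration_years) {
  out <- ifelse(is.na(ert_status), NA_character_,
                ifelse(ert_status == "untreated", "untreated",
                       ifelse(!is.na(ert_duration_years) &
                                ert_duration_years > 3, "gt3y", "le3y")))
  factor(out, levels = c("untreated", "le3y", "gt3y"))
}

#' Subgroup specification
#'
#' A named predicate over the merged per-patient table (change scores joined
#' with the cohort table and, when available, initial-visit outcomes as
#' `<outcome>_initial` columns).
#'
#' @param name Subgroup label.
#' @param predicate Function taking the merged data.frame and returning a
#'   logical vector (patients only are offered).
#' @return Object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(name, predicate) {
  stopifnot(is.function(predicate))
  structure(list(name = name, predicate = predicate), class = "subgroup_spec")
}

#' Standard subgroup axes
#'
#' `ert_subgroups()` returns the three treatment-duration subgroups;
#' `weakness_subgroups()` splits patients at the initial cranial-caudal
#' ratio (default cut-off 1.4, the lowest value recorded in healthy
#' controls: below it, moderate-to-severe diaphragmatic weakness).
#'
#' @param cutoff Cranial-caudal ratio cut-off.
#' @return List of [subgroup_spec()]s.
#' @export
ert_subgroups <- function() {
  mk <- function(nm, lev) subgroup_spec(nm, function(df) {
    !is.na(df$ert_group) & df$ert_group == lev
  })
  list(untreated = mk("untreated", "untreated"),
       le3y = mk("ERT <= 3 years", "le3y"),
       gt3y = mk("ERT > 3 years", "gt3y"))
}

#' @rdname ert_subgroups
#' @export
weakness_subgroups <- function(cutoff = 1.4) {
  list(
    weak = subgroup_spec(sprintf("cranial-caudal ratio < %.1f", cutoff),
                         function(df) {
                           !is.na(df$cranial_caudal_ratio_initial) &
                             df$cranial_caudal_ratio_initial < cutoff
                         }),
    mild = subgroup_spec(sprintf("cranial-caudal ratio >= %.1f", cutoff),
                         function(df) {
                           !is.na(df$cranial_caudal_ratio_initial) &
                             df$cranial_caudal_ratio_initial >= cutoff
                         }))
}

# Merge change scores with cohort covariates and initial-visit outcomes.
patient_frame <- function(outcomes, cohort) {
  ch <- change_scores(outcomes)
  if (!is.null(cohort)) {
    keep <- setdiff(names(cohort), "group")
    ch <- merge(ch, cohort[keep], by = "id", all.x = TRUE, sort = FALSE)
    if (all(c("ert_status", "ert_duration_years") %in% names(ch)))
      ch$ert_group <- ert_group(ch$ert_status, ch$ert_duration_years)
  }
  ini <- outcomes[outcomes$visit == "initial", ]
  for (v in intersect(OUTCOME_NAMES, names(ini)))
    ch[[paste0(v, "_initial")]] <- ini[[v]][match(ch$id, ini$id)]
  ch
}

#' Subgroup analysis against controls
#'
#' Tests a patient subgroup's change scores against the healthy controls'
#' change scores with the Mann-Whitney test, without multiplicity
#' adjustment (the study's explicit choice for these indicative analyses).
#'
#' @param outcomes An `outcomes_table` with both visits.
#' @param cohort A `cohort_table` (needed for treatment subgroups; may be
#'   `NULL` for weakness subgroups).
#' @param spec A [subgroup_spec()].
#' @param outcome Outcome column to analyse (default diaphragm height
#'   ratio change).
#' @return A `comparison_result`; its `n` reports subgroup and control
#'   sizes.
#' @export
subgroup_analysis <- function(outcomes, cohort, spec,
                              outcome = "diaphragm_height_ratio") {
  stopifnot(inherits(spec, "subgroup_spec"))
  df <- patient_frame(outcomes, cohort)
  pat <- df[df$group == "patient", ]
  sel <- spec$predicate(pat)
  if (!any(sel, na.rm = TRUE))
    stop("empty subgroup: ", spec$name)
  sub_vals <- pat[[outcome]][which(sel)]
  ctrl_vals <- df[[outcome]][df$group == "control"]
  res <- mann_whitney(sub_vals, ctrl_vals,
                      variable = paste0(outcome, " change: ", spec$name,
                                        " vs controls"))
  res$subgroup <- spec$name
  res
}

fmt_mmr <- function(x, digits = 2) {
  if (all(is.na(x))) return(NA_character_)
  sprintf("%.*f (%.*f to %.*f)", digits, x["median"], digits, x["min"],
          digits, x["max"])
}

group_comparison_rows <- function(ini, chg, vars, digits = 2) {
  do.call(rbind, lapply(vars, function(v) {
    pi <- ini[[v]][ini$group == "patient"]
    ci <- ini[[v]][ini$group == "control"]
    pc <- chg[[v]][chg$group == "patient"]
    cc <- chg[[v]][chg$group == "control"]
    r1 <- mann_whitney(pi, ci, v)
    r2 <- mann_whitney(pc, cc, v)
    data.frame(
      variable = v,
      patients_initial = fmt_mmr(median_range(pi), digits),
      controls_initial = fmt_mmr(median_range(ci), digits),
      p_initial = r1$p,
      sig_initial = ifelse(r1$p <= 0.05, "*", ""),
      patients_change = fmt_mmr(median_range(pc), digits),
      controls_change = fmt_mmr(median_range(cc), digits),
      p_change = r2$p,
      sig_change = ifelse(r2$p <= 0.05, "*", ""),
      patients_initial_median = unname(median_range(pi)["median"]),
      controls_initial_median = unname(median_range(ci)["median"]),
      patients_change_median = unname(median_range(pc)["median"]),
      controls_change_median = unname(median_range(cc)["median"]),
      stringsAsFactors = FALSE)
  }))
}

#' Study-style cohort reports
#'
#' Builds the three standard reports from a per-subject outcomes table and a
#' cohort table: baseline characteristics with group comparisons
#' (chi-square for sex, Mann-Whitney otherwise), pulmonary-function
#' outcomes (initial and one-year change), and MRI outcomes (initial and
#' one-year change), plus a per-patient classification
#' (treatment-duration group, initial weakness class at the cranial-caudal
#' cut-off, and deterioration/improvement label of the height-ratio
#' change). Significance is marked at p <= 0.05. Missing variables are
#' listed and the remaining tables are still produced.
#'
#' @param outcomes An `outcomes_table` with both visits (optionally with
#'   `fvc_upright`, `fvc_supine`, `mip`, `mep` columns).
#' @param cohort A `cohort_table`.
#' @param cutoff Cranial-caudal weakness cut-off (default 1.4).
#' @param exclude_ids Subject ids to drop before computing (e.g. an outlier
#'   sensitivity rerun).
#' @return List of class `cohort_report`: `baseline`, `pft`, `mri`,
#'   `classification`, `missing_variables`.
#' @export
reproduce_tables <- function(outcomes, cohort, cutoff = 1.4,
                             exclude_ids = NULL) {
  stopifnot(is.data.frame(outcomes), is.data.frame(cohort))
  if (!is.null(exclude_ids)) {
    outcomes <- outcomes[!outcomes$id %in% exclude_ids, ]
    cohort <- cohort[!cohort$id %in% exclude_ids, ]
  }
  grp <- cohort$group
  pat <- cohort[grp == "patient", ]
  ctl <- cohort[grp == "control", ]

  baseline_rows <- list()
  if ("sex" %in% names(cohort)) {
    tab <- rbind(patient = c(sum(pat$sex == "M"), sum(pat$sex == "F")),
                 control = c(sum(ctl$sex == "M"), sum(ctl$sex == "F")))
    r <- chi_square_2x2(tab, "sex (male/female)")
    baseline_rows$sex <- data.frame(
      variable = "sex, males (%)",
      patients = sprintf("%d (%.0f%%)", tab[1, 1], 100 * tab[1, 1] / nrow(pat)),
      controls = sprintf("%d (%.0f%%)", tab[2, 1], 100 * tab[2, 1] / nrow(ctl)),
      p = r$p, sig = ifelse(r$p <= 0.05, "*", ""), stringsAsFactors = FALSE)
  }
  cont_vars <- intersect(c("age_years", "height_cm", "weight_kg", "bmi",
                           "followup_years"), {
    if (all(c("weight_kg", "height_cm") %in% names(cohort)))
      cohort$bmi <- cohort$weight_kg / (cohort$height_cm / 100)^2
    names(cohort)
  })
  if (all(c("weight_kg", "height_cm") %in% names(cohort)))
    cohort$bmi <- cohort$weight_kg / (cohort$height_cm / 100)^2
  for (v in cont_vars) {
    a <- cohort[[v]][grp == "patient"]; b <- cohort[[v]][grp == "control"]
    if (all(is.na(a)) || all(is.na(b))) next
    r <- mann_whitney(a, b, v)
    baseline_rows[[v]] <- data.frame(
      variable = v,
      patients = fmt_mmr(median_range(a)),
      controls = fmt_mmr(median_range(b)),
      p = r$p, sig = ifelse(r$p <= 0.05, "*", ""), stringsAsFactors = FALSE)
  }
  if (all(c("ert_status", "ert_duration_years") %in% names(cohort))) {
    eg <- ert_group(pat$ert_status, pat$ert_duration_years)
    for (lev in levels(eg)) {
      sel <- !is.na(eg) & eg == lev
      dur <- pat$ert_duration_years[sel]
      baseline_rows[[paste0("ert_", lev)]] <- data.frame(
        variable = paste0("patients ", c(untreated = "without ERT",
                                         le3y = "<= 3 years ERT",
                                         gt3y = "> 3 years ERT")[lev]),
        patients = sprintf("%d (%.0f%%)%s", sum(sel),
                           100 * sum(sel) / nrow(pat),
                           if (lev == "untreated" || all(is.na(dur))) ""
                           else paste0(", duration ",
                                       fmt_mmr(median_range(dur), 1))),
        controls = "-", p = NA_real_, sig = "", stringsAsFactors = FALSE)
    }
  }
  baseline <- do.call(rbind, c(baseline_rows, list(make.row.names = FALSE)))

  ini <- outcomes[outcomes$visit == "initial", ]
  chg <- change_scores(outcomes)
  pft_vars <- intersect(c("fvc_upright", "fvc_supine", "mip", "mep"),
                        names(outcomes))
  pft <- if (length(pft_vars)) group_comparison_rows(ini, chg, pft_vars, 1)
         else NULL
  mri_vars <- intersect(OUTCOME_NAMES, names(outcomes))
  missing_vars <- setdiff(OUTCOME_NAMES, names(outcomes))
  mri <- if (length(mri_vars)) group_comparison_rows(ini, chg, mri_vars, 2)
         else NULL

  pf <- patient_frame(outcomes, cohort)
  pf <- pf[pf$group == "patient", ]
  classification <- data.frame(
    id = pf$id,
    ert_group = if ("ert_group" %in% names(pf)) as.character(pf$ert_group)
                else NA_character_,
    cc_initial = pf$cranial_caudal_ratio_initial,
    weakness = ifelse(is.na(pf$cranial_caudal_ratio_initial), "unknown",
                      ifelse(pf$cranial_caudal_ratio_initial < cutoff,
                             "moderate-severe", "mild-none")),
    height_ratio_change = pf$diaphragm_height_ratio,
    change_class = classify_change(pf$diaphragm_height_ratio),
    stringsAsFactors = FALSE)

  structure(list(baseline = baseline, pft = pft, mri = mri,
                 classification = classification,
                 missing_variables = missing_vars),
            class = "cohort_report")
}
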