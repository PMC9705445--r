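# Longitudinal cohort simulator.
#
# Emulates the study design: each subject is scanned at two visits one year
# apart, each visit yielding an expiration/inspiration phantom pair. Disease
# is encoded geometrically: patients draw smaller diaphragm descents (lower
# cranial-caudal ratios) and a group-specific additive one-year drift of the
# dome-height ratio (positive in patients, zero in controls by default).
# Measurement noise acts on the geometry parameters, never on the voxel
# masks, so each subject-visit keeps an exact analytic truth.

#' Cohort simulation specification
#'
#' @param n_patients,n_controls Group sizes (default 30 and 10, the study's
#'   design).
#' @param drift Named vector: additive one-year change of the dome-height
#'   ratio per group. Defaults to `c(patient = 0.04, control = 0)`, the
#'   patient median change reported for this outcome and a stable control
#'   group.
#' @param noise Standard deviation of the per-visit measurement noise on the
#'   dome-height ratio (geometry-level; default 0.025, calibrated so a 0.05
#'   one-year drift is detectable in the default design -- see the methods
#'   vignette). Small positional jitter (sd 1 mm) on base/apex levels models
#'   repositioning.
#' @param baseline Per-group baseline distributions: for each group a list
#'   with `height_ratio = c(mean, sd)` and `descent = c(min, max)` mm.
#' @param spacing Default rasterization spacing in mm (scalar or length 3).
#' @param seed Integer seed; all draws flow from it.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_patients = 30, n_controls = 10,
                            drift = c(patient = 0.04, control = 0),
                            noise = 0.025,
                            baseline = list(
                              patient = list(height_ratio = c(1.19, 0.25),
                                             descent = c(25, 45)),
                              control = list(height_ratio = c(1.12, 0.12),
                                             descent = c(45, 65))),
                            spacing = 3,
                            seed = NULL) {
  stopifnot(n_patients >= 1, n_controls >= 1, noise >= 0,
            all(c("patient", "control") %in% names(drift)),
            all(c("patient", "control") %in% names(baseline)))
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 drift = drift, noise = noise, baseline = baseline,
                 spacing = spacing, seed = seed),
            class = "cohort_sim_spec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

rtruncnorm1 <- function(mean, sd, lo, hi) clamp(rnorm(1, mean, sd), lo, hi)

# Draw the per-subject geometry (visit-independent part).
draw_subject_geometry <- function(group, base) {
  list(
    A = runif(1, 50, 60),                 # envelope right-left semi-axis
    B_e = runif(1, 62, 72),               # expiratory envelope AP semi-axis
    ap_ratio = rtruncnorm1(1.27, 0.05, 1.10, 1.45),
    base_e = 80,
    cc0 = runif(1, 100, 130),             # expiratory cranial-caudal extent
    descent = runif(1, base$descent[1], base$descent[2]),
    apex_rise = runif(1, 5, 15),
    h_e = runif(1, 26, 34),               # expiratory dome height
    r1 = rtruncnorm1(base$height_ratio[1], base$height_ratio[2], 0.6, 2.2)
  )
}

# Visit-level geometry: drift + measurement noise + repositioning jitter +
# an integer-multiple-of-3mm rigid translation at the follow-up visit.
draw_visit_geometry <- function(geom, visit, drift, noise) {
  jit <- function(sd = 1) rnorm(1, 0, sd)
  r <- clamp(geom$r1 + (visit - 1) * drift + rnorm(1, 0, noise), 0.45, 2.6)
  base_e <- geom$base_e + jit()
  list(
    height_ratio = r,
    ap_ratio = clamp(geom$ap_ratio + rnorm(1, 0, noise), 1.05, 1.5),
    base_e = base_e,
    apex_e = base_e + geom$cc0 + jit(),
    descent = geom$descent + jit(),
    apex_rise = geom$apex_rise + jit(),
    shift = if (visit == 1) c(0, 0, 0) else 3 * sample(-3:3, 3, replace = TRUE)
  )
}

#' Phantom parameters for one simulated subject-visit
#'
#' @param geom A subject entry of a [simulate_cohort()] result (element of
#'   `$subjects`).
#' @param visit 1 (initial) or 2 (follow-up).
#' @param spacing Rasterization spacing in mm; defaults to the simulation
#'   spec's spacing.
#' @return A [phantom_params()] object.
#' @export
subject_phantom_params <- function(geom, visit, spacing = NULL) {
  v <- geom$visits[[visit]]
  if (is.null(spacing)) spacing <- geom$spacing
  a <- geom$A - 6
  b <- geom$B_e - 6
  B_i <- geom$B_e * v$ap_ratio
  h_i <- v$height_ratio * geom$h_e
  base_i <- v$base_e - v$descent
  phantom_params(
    spacing = spacing,
    box = c(300, 240, 260),
    lung_offset = 75,
    envelope = list(expiration = c(geom$A, geom$B_e),
                    inspiration = c(geom$A, B_i)),
    dome = list(
      expiration = dome_spec(v$base_e, geom$h_e, c(a, b)),
      inspiration = dome_spec(base_i, h_i, c(a, b))),
    apex = c(expiration = v$apex_e, inspiration = v$apex_e + v$apex_rise),
    ap_center = 120,
    shift = v$shift)
}

sample_sex <- function(n, prop_male) {
  n_m <- round(prop_male * n)
  sample(c(rep("M", n_m), rep("F", n - n_m)))
}

# ERT allocation mirrors the study's proportions: 7/30 untreated,
# 8/30 treated <= 3 years, 15/30 treated > 3 years at the initial MRI.
sample_ert <- function(n) {
  counts <- round(c(7, 8, 15) / 30 * n)
  counts[3] <- n - sum(counts[1:2])
  grp <- sample(rep(c("untreated", "le3y", "gt3y"), counts))
  dur <- ifelse(grp == "untreated", NA_real_,
                ifelse(grp == "le3y", runif(n, -0.1, 3.0),
                       runif(n, 3.7, 12.8)))
  list(status = ifelse(grp == "untreated", "untreated", "treated"),
       duration = dur)
}

#' Simulate a two-visit cohort
#'
#' Draws per-subject baseline geometry and two visit geometries under the
#' group drift and noise model of `spec`, plus a demographic/clinical table
#' and per-visit pulmonary-function values. Masks are not rasterized here;
#' use [measure_cohort()] (full image pipeline) or [analytic_outcomes()]
#' (closed-form measurement model) on the result.
#'
#' @param spec A [cohort_sim_spec()].
#' @return An object of class `cohort_sim`: list with `spec`, `cohort` (a
#'   `cohort_table` data.frame), `subjects` (per-subject geometry and
#'   analytic truths) and `pft` (per-visit percent-predicted values).
#' @export
simulate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$seed, {
    groups <- c(rep("patient", spec$n_patients),
                rep("control", spec$n_controls))
    ids <- c(sprintf("P%02d", seq_len(spec$n_patients)),
             sprintf("C%02d", seq_len(spec$n_controls)))
    subjects <- vector("list", length(ids))
    names(subjects) <- ids
    for (s in seq_along(ids)) {
      g <- groups[s]
      geom <- draw_subject_geometry(g, spec$baseline[[g]])
      geom$group <- g
      geom$id <- ids[s]
      geom$spacing <- spec$spacing
      geom$visits <- lapply(1:2, function(v)
        draw_visit_geometry(geom, v, spec$drift[[g]], spec$noise))
      geom$truth <- lapply(1:2, function(v)
        analytic_truth(subject_phantom_params(geom, v)))
      subjects[[s]] <- geom
    }
    is_p <- groups == "patient"
    ert <- sample_ert(spec$n_patients)
    cohort <- data.frame(
      id = ids, group = groups,
      sex = c(sample_sex(spec$n_patients, 14 / 30),
              sample_sex(spec$n_controls, 5 / 10)),
      age_years = round(ifelse(is_p, runif(length(ids), 17, 70),
                               runif(length(ids), 25, 63))),
      height_cm = round(runif(length(ids), 157, 201)),
      weight_kg = round(runif(length(ids), 55, 99)),
      ert_status = c(ert$status, rep(NA_character_, spec$n_controls)),
      ert_duration_years = round(c(ert$duration,
                                   rep(NA_real_, spec$n_controls)), 2),
      followup_years = round(ifelse(is_p, runif(length(ids), 0.9, 1.2),
                                    runif(length(ids), 1.0, 1.3)), 2),
      stringsAsFactors = FALSE)
    class(cohort) <- c("cohort_table", "data.frame")
    # percent-predicted pulmonary function, stable over the year up to noise
    pft_base <- data.frame(
      id = rep(ids, each = 2),
      visit = rep(VISIT_LEVELS, length(ids)),
      stringsAsFactors = FALSE)
    base_fvc <- ifelse(is_p, runif(length(ids), 67, 119),
                       runif(length(ids), 93, 114))
    pft_base$fvc_upright <- round(rep(base_fvc, each = 2) +
                                    rnorm(nrow(pft_base), 0, 2), 1)
    pft_base$fvc_supine <- round(pft_base$fvc_upright -
                                   rep(ifelse(is_p, runif(length(ids), 0, 30),
                                              runif(length(ids), 0, 8)),
                                       each = 2) +
                                   rnorm(nrow(pft_base), 0, 2), 1)
    pft_base$mip <- round(rep(ifelse(is_p, runif(length(ids), 37, 127),
                                     runif(length(ids), 54, 131)), each = 2) +
                            rnorm(nrow(pft_base), 0, 4), 1)
    pft_base$mep <- round(rep(ifelse(is_p, runif(length(ids), 35, 149),
                                     runif(length(ids), 67, 132)), each = 2) +
                            rnorm(nrow(pft_base), 0, 4), 1)
    structure(list(spec = spec, cohort = cohort, subjects = subjects,
                   pft = pft_base),
              class = "cohort_sim")
  })
}

sim_outcomes_frame <- function(sim, ratio_fun) {
  rows <- lapply(sim$subjects, function(geom) {
    do.call(rbind, lapply(1:2, function(v) {
      r <- ratio_fun(geom, v)
      data.frame(id = geom$id, group = geom$group, visit = VISIT_LEVELS[v],
                 as.list(r[OUTCOME_NAMES]), stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  df <- merge(df, sim$pft, by = c("id", "visit"), sort = FALSE)
  df <- df[order(match(df$id, names(sim$subjects)),
                 match(df$visit, VISIT_LEVELS)), ]
  rownames(df) <- NULL
  df <- df[, c("id", "group", "visit", OUTCOME_NAMES,
               setdiff(names(df), c("id", "group", "visit", OUTCOME_NAMES)))]
  class(df) <- c("outcomes_table", "data.frame")
  df
}

#' Closed-form outcomes of a simulated cohort
#'
#' Evaluates the analytic truth of each subject-visit geometry: the
#' measurement-model route, free of voxelization error. Useful for fast
#' replicate studies (power, type-I behaviour).
#'
#' @param sim A [simulate_cohort()] result.
#' @return An `outcomes_table` data.frame (one row per subject-visit).
#' @export
analytic_outcomes <- function(sim) {
  stopifnot(inherits(sim, "cohort_sim"))
  sim_outcomes_frame(sim, function(geom, v) geom$truth[[v]]$ratios)
}

#' Measure a simulated cohort through the image pipeline
#'
#' Rasterizes each subject-visit phantom pair and runs the full measurement
#' chain ([compute_subject()]): level selection on the initial expiratory
#' right lung, cross-visit level matching by integer-shift Dice
#' registration, and all eight outcomes per visit.
#'
#' @param sim A [simulate_cohort()] result.
#' @param spacing Optional spacing override (mm, scalar or length 3) for the
#'   rasterization.
#' @return List with `outcomes` (an `outcomes_table`), `changes` (one row per
#'   subject: follow-up minus initial per outcome) and `match` (per-subject
#'   level-matching diagnostics).
#' @export
measure_cohort <- function(sim, spacing = NULL) {
  stopifnot(inherits(sim, "cohort_sim"))
  res <- lapply(sim$subjects, function(geom) {
    pair1 <- build_phantom_pair(subject_phantom_params(geom, 1, spacing))
    pair2 <- build_phantom_pair(subject_phantom_params(geom, 2, spacing))
    compute_subject(pair1, pair2)
  })
  out <- sim_outcomes_frame(sim, function(geom, v) {
    m <- res[[geom$id]][[c("initial", "followup")[v]]]
    m$ratios
  })
  changes <- do.call(rbind, lapply(names(res), function(id) {
    data.frame(id = id, group = sim$subjects[[id]]$group,
               as.list(res[[id]]$change), stringsAsFactors = FALSE)
  }))
  rownames(changes) <- NULL
  match_info <- do.call(rbind, lapply(names(res), function(id) {
    r <- res[[id]]
    data.frame(id = id, level_initial = r$level_initial,
               level_followup = r$level_followup,
               shift_lr = r$match$shift[1], dice = r$match$dice,
               fallback = r$match$fallback, stringsAsFactors = FALSE)
  }))
  list(outcomes = out, changes = changes, match = match_info)
}

#' Power to detect a one-year drift difference
#'
#' Replicates the study design (default 30 patients / 10 controls) under the
#' closed-form measurement model and reports the fraction of cohorts in
#' which the Mann-Whitney test on the height-ratio change scores flags the
#' patient-control difference at p <= 0.05.
#'
#' @param n_replicates Number of simulated cohorts.
#' @param drift Per-group one-year drift passed to [cohort_sim_spec()].
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param n_patients,n_controls Group sizes.
#' @param alpha Significance level.
#' @return List with `power` (fraction significant) and `p_values`.
#' @export
drift_detection_power <- function(n_replicates = 100,
                                  drift = c(patient = 0.05, control = 0),
                                  seed = 1L, n_patients = 30, n_controls = 10,
                                  alpha = 0.05) {
  p_values <- vapply(seq_len(n_replicates), function(r) {
    spec <- cohort_sim_spec(n_patients = n_patients, n_controls = n_controls,
                            drift = drift, seed = seed + r)
    ch <- change_scores(analytic_outcomes(simulate_cohort(spec)))
    mann_whitney(ch$diaphragm_height_ratio[ch$group == "patient"],
                 ch$diaphragm_height_ratio[ch$group == "control"])$p
  }, numeric(1))
  list(power = mean(p_values <= alpha), p_values = p_values)
}
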