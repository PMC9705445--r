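# The eight inspiration/expiration outcomes.
#
# 3D outcomes (lung volume ratio, diaphragm volume ratio) are computed on
# the full two-lung masks. 2D outcomes (lung area, cranial-caudal and
# anterior-posterior extents, their quotient, dome height and dome area) are
# computed on the sagittal slice through the middle of the right lung's
# right-left extent, selected on the expiratory mask of each visit and
# matched across visits by exhaustive integer-shift Dice registration.
# Undefined outcomes are carried as NA with a reason code, never dropped
# silently.

#' Lung volume in mm^3
#'
#' Voxel count times voxel volume.
#'
#' @param mask A `mask_volume`.
#' @return Volume in mm^3.
#' @export
lung_volume <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  n <- sum(mask$data)
  if (n == 0) stop("empty mask")
  n * voxel_volume(mask)
}

#' Lung volume ratio (inspiration / expiration)
#'
#' Outcome (1): the relative increase in total lung volume from
#' end-expiration to end-inspiration.
#'
#' @param pair A [breath_pair()].
#' @return Dimensionless ratio.
#' @export
volume_ratio <- function(pair) {
  stopifnot(inherits(pair, "breath_pair"))
  ve <- lung_volume(pair$expiration)
  if (ve <= 0) stop("zero expiratory volume")
  lung_volume(pair$inspiration) / ve
}

#' Diaphragm surface of a lung mask
#'
#' For every (right-left, anterior-posterior) column that contains lung, the
#' caudal-most lung voxel index along the cranio-caudal axis. This is the
#' discrete diaphragm surface the displaced-volume outcome integrates over.
#'
#' @param mask A `mask_volume` (one or both lungs).
#' @return Integer matrix of dim `dim(mask)[1:2]`; `NA` where the column
#'   holds no lung.
#' @export
diaphragm_surface <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  d <- dim(mask$data)
  surf <- matrix(NA_integer_, d[1], d[2])
  # sweep cranial -> caudal so the last assignment is the caudal-most index
  for (k in rev(seq_len(d[3]))) {
    sl <- mask$data[, , k]
    surf[sl] <- k
  }
  surf
}

#' Diaphragm volume ratio
#'
#' Outcome (2): the fraction of the inspiratory lung-volume gain displaced by
#' the diaphragm. The numerator integrates, over all columns where both
#' phases have a diaphragm surface, the caudal descent of the surface
#' (expiration minus inspiration, clamped at 0) times the voxel
#' cross-section; the denominator is the total volume gain V_insp - V_exp.
#'
#' @param pair A [breath_pair()].
#' @return Dimensionless ratio, or `NA` with attribute `reason` when the
#'   volume gain is not positive.
#' @export
diaphragm_volume_ratio <- function(pair) {
  stopifnot(inherits(pair, "breath_pair"))
  ve <- lung_volume(pair$expiration)
  vi <- lung_volume(pair$inspiration)
  if (vi <= ve) {
    out <- NA_real_
    attr(out, "reason") <- "non-positive lung volume gain"
    return(out)
  }
  sp <- pair$expiration$spacing
  se <- diaphragm_surface(pair$expiration)
  si <- diaphragm_surface(pair$inspiration)
  shared <- !is.na(se) & !is.na(si)
  drop_mm <- (se[shared] - si[shared]) * sp[3]
  swept <- sum(pmax(0, drop_mm)) * sp[1] * sp[2]
  swept / (vi - ve)
}

axis_extent <- function(flags) {
  idx <- which(flags)
  if (!length(idx)) return(NULL)
  c(min(idx), max(idx))
}

#' Select the right mid hemi-diaphragm sagittal level
#'
#' The sagittal plane through the midpoint of the right lung's right-left
#' extent on the expiratory mask.
#'
#' @param right_lung_exp `mask_volume` of the expiratory right lung.
#' @return Integer slice index along axis 1 (1-based).
#' @export
select_sagittal_level <- function(right_lung_exp) {
  stopifnot(inherits(right_lung_exp, "mask_volume"))
  ext <- axis_extent(apply(right_lung_exp$data, 1, any))
  if (is.null(ext)) stop("empty right-lung mask")
  as.integer(floor((ext[1] + ext[2]) / 2 + 0.5))
}

# Cross-correlation of two binary grids over all integer shifts, via FFT.
# Returns overlap counts for shifts in [-window, window]^3.
shift_overlaps <- function(a, b, window) {
  d <- dim(a)
  padded <- vapply(d + 2L * window, stats::nextn, integer(1),
                   factors = c(2L, 3L, 5L))
  pa <- array(0, padded); pb <- array(0, padded)
  pa[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  pb[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- b
  # overlap(s) = sum_v a(v) * b(v + s) = IFFT(conj(FFT(a)) * FFT(b)) at s
  cc <- Re(fft(Conj(fft(pa)) * fft(pb), inverse = TRUE)) / prod(padded)
  wrap <- function(s, n) ifelse(s >= 0, s + 1L, n + s + 1L)
  shifts <- expand.grid(sx = -window:window, sy = -window:window,
                        sz = -window:window)
  shifts$overlap <- cc[cbind(wrap(shifts$sx, padded[1]),
                             wrap(shifts$sy, padded[2]),
                             wrap(shifts$sz, padded[3]))]
  shifts
}

#' Match sagittal levels across visits
#'
#' Exhaustive integer-shift search (within `window` voxels per axis)
#' maximizing the Dice overlap between the initial and follow-up expiratory
#' right-lung masks; the follow-up level is the initial level plus the best
#' right-left shift. Ties are broken toward the zero shift (smallest L1
#' norm, then lexicographically). When even the best Dice is below 0.5 the
#' match is considered unreliable and the level is re-selected on the
#' follow-up mask instead.
#'
#' @param exp_initial,exp_followup Expiratory right-lung `mask_volume`s on
#'   grids of equal shape.
#' @param level_initial Slice level selected on the initial visit.
#' @param window Search half-width in voxels (default 10).
#' @return List with `level` (follow-up slice level), `shift` (length-3
#'   integer vector, follow-up relative to initial), `dice`, and `fallback`
#'   (logical).
#' @export
match_visits <- function(exp_initial, exp_followup, level_initial,
                         window = 10L) {
  stopifnot(inherits(exp_initial, "mask_volume"),
            inherits(exp_followup, "mask_volume"),
            identical(dim(exp_initial$data), dim(exp_followup$data)))
  na <- sum(exp_initial$data); nb <- sum(exp_followup$data)
  if (na == 0 || nb == 0) stop("empty mask in visit matching")
  sh <- shift_overlaps(exp_initial$data, exp_followup$data, window)
  sh$dice <- 2 * sh$overlap / (na + nb)
  ord <- order(-sh$dice, abs(sh$sx) + abs(sh$sy) + abs(sh$sz),
               abs(sh$sx), abs(sh$sy), abs(sh$sz), sh$sx, sh$sy, sh$sz)
  best <- sh[ord[1], ]
  if (best$dice < 0.5) {
    warning("visit matching unreliable (best Dice ",
            sprintf("%.2f", best$dice),
            " < 0.5); falling back to level selection on the follow-up scan")
    return(list(level = select_sagittal_level(exp_followup),
                shift = c(NA_integer_, NA_integer_, NA_integer_),
                dice = best$dice, fallback = TRUE))
  }
  list(level = as.integer(level_initial + best$sx),
       shift = as.integer(c(best$sx, best$sy, best$sz)),
       dice = best$dice, fallback = FALSE)
}

#' Sagittal slice extent outcomes
#'
#' Outcomes (3)-(6) on the right mid hemi-diaphragm slice: lung area (pixel
#' count times pixel area), cranial-caudal extent (inclusive index span
#' along the cranio-caudal axis times spacing; diaphragm motion),
#' anterior-posterior extent (chest-wall motion), each as an
#' inspiration/expiration ratio, plus the CC-AP ratio (their quotient).
#'
#' @param pair A [breath_pair()].
#' @param level Sagittal slice index (axis 1).
#' @return Named numeric vector (`lung_area_ratio`, `cranial_caudal_ratio`,
#'   `anterior_posterior_ratio`, `cc_ap_ratio`), `NA` with attribute
#'   `reason` when a slice is empty.
#' @export
slice_extent_ratios <- function(pair, level) {
  stopifnot(inherits(pair, "breath_pair"))
  sp <- pair$expiration$spacing
  vals <- lapply(PHASES, function(phase) {
    sl <- pair[[phase]]$data[level, , ]
    if (!any(sl)) return(NULL)
    cc <- axis_extent(apply(sl, 2, any))
    ap <- axis_extent(apply(sl, 1, any))
    c(area = sum(sl) * sp[2] * sp[3],
      cc = (cc[2] - cc[1] + 1) * sp[3],
      ap = (ap[2] - ap[1] + 1) * sp[2])
  })
  names(vals) <- PHASES
  if (is.null(vals$expiration) || is.null(vals$inspiration)) {
    out <- stats::setNames(rep(NA_real_, 4),
                           c("lung_area_ratio", "cranial_caudal_ratio",
                             "anterior_posterior_ratio", "cc_ap_ratio"))
    attr(out, "reason") <- "empty sagittal slice"
    return(out)
  }
  r <- vals$inspiration / vals$expiration
  c(lung_area_ratio = unname(r["area"]),
    cranial_caudal_ratio = unname(r["cc"]),
    anterior_posterior_ratio = unname(r["ap"]),
    cc_ap_ratio = unname(r["cc"] / r["ap"]))
}

#' Dome geometry of a sagittal slice
#'
#' Extracts the diaphragm contour (per anterior-posterior column, the
#' caudal-most lung pixel, in mm), the chord joining the posterior-most and
#' anterior-most contour points, the dome height (maximum perpendicular
#' distance from the contour to the chord line) and the dome area (absolute
#' shoelace area of the polygon closed by the chord).
#'
#' @param slice 2D logical matrix (anterior-posterior by cranio-caudal axes)
#'   at a fixed sagittal level.
#' @param spacing Length-2 pixel spacing in mm (anterior-posterior,
#'   cranio-caudal).
#' @return List of class `dome_geometry` with `contour` (n x 2 matrix of
#'   (y, z) mm coordinates), `chord` (2 x 2 matrix), `height` (mm) and
#'   `area` (mm^2); or `NA` with attribute `reason` if the contour has fewer
#'   than 3 points.
#' @export
dome_geometry <- function(slice, spacing) {
  stopifnot(is.matrix(slice), length(spacing) == 2L)
  cols <- which(apply(slice, 1, any))
  if (length(cols) < 3L) {
    out <- NA
    attr(out, "reason") <- "diaphragm contour has fewer than 3 points"
    return(out)
  }
  zidx <- vapply(cols, function(j) which(slice[j, ])[1], integer(1))
  contour <- cbind(y = (cols - 1) * spacing[1], z = (zidx - 1) * spacing[2])
  p1 <- contour[1, ]; p2 <- contour[nrow(contour), ]   # posterior, anterior
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  if (len == 0) {
    out <- NA
    attr(out, "reason") <- "degenerate chord"
    return(out)
  }
  # perpendicular distance of each contour point from the chord line
  d <- abs(v[1] * (contour[, 2] - p1[2]) - v[2] * (contour[, 1] - p1[1])) / len
  # shoelace area of the closed polygon (contour path, chord return)
  y <- contour[, 1]; z <- contour[, 2]
  area <- abs(sum(y * c(z[-1], z[1]) - c(y[-1], y[1]) * z)) / 2
  structure(list(contour = contour, chord = rbind(p1, p2),
                 height = max(d), area = area),
            class = "dome_geometry")
}

#' Diaphragm curvature outcomes
#'
#' Outcomes (7)-(8): inspiration/expiration ratios of the dome height and
#' dome area on the matched sagittal slice. An increase over time signals
#' insufficient diaphragmatic contraction (the dome bulges further cranially
#' during inspiration instead of flattening). Undefined when the expiratory
#' dome is flatter than one voxel.
#'
#' @param pair A [breath_pair()].
#' @param level Sagittal slice index (axis 1).
#' @return Named numeric vector (`diaphragm_height_ratio`,
#'   `diaphragm_area_ratio`); `NA` with attribute `reason` when undefined.
#' @export
curvature_ratios <- function(pair, level) {
  stopifnot(inherits(pair, "breath_pair"))
  sp <- pair$expiration$spacing[2:3]
  und <- function(reason) {
    out <- stats::setNames(rep(NA_real_, 2),
                           c("diaphragm_height_ratio", "diaphragm_area_ratio"))
    attr(out, "reason") <- reason
    out
  }
  ge <- dome_geometry(pair$expiration$data[level, , ], sp)
  gi <- dome_geometry(pair$inspiration$data[level, , ], sp)
  if (!inherits(ge, "dome_geometry"))
    return(und(paste0("expiration: ", attr(ge, "reason"))))
  if (!inherits(gi, "dome_geometry"))
    return(und(paste0("inspiration: ", attr(gi, "reason"))))
  if (ge$height < sp[2])
    return(und("expiratory dome flatter than one voxel"))
  c(diaphragm_height_ratio = gi$height / ge$height,
    diaphragm_area_ratio = gi$area / ge$area)
}

#' All eight outcomes of one visit
#'
#' Convenience wrapper computing the 3D outcomes on the full masks and the
#' 2D outcomes at the given (or automatically selected) sagittal level.
#'
#' @param pair A [breath_pair()] (two-lung masks).
#' @param level Sagittal slice index; if `NULL`, selected via
#'   [select_sagittal_level()] on the expiratory right lung.
#' @return Object of class `subject_measures`: list with `ratios` (named
#'   vector over [outcome_names()]), `raw` (per-phase lung volume, slice
#'   area, extents, dome height/area), `level`, and `reasons` (named list of
#'   reason codes for undefined outcomes).
#' @export
compute_measures <- function(pair, level = NULL) {
  stopifnot(inherits(pair, "breath_pair"))
  if (is.null(level)) {
    sides <- split_sides(pair$expiration)
    level <- select_sagittal_level(sides$right)
  }
  reasons <- list()
  dvr <- diaphragm_volume_ratio(pair)
  if (is.na(dvr)) reasons$diaphragm_volume_ratio <- attr(dvr, "reason")
  ext <- slice_extent_ratios(pair, level)
  if (anyNA(ext))
    reasons[names(ext)] <- attr(ext, "reason")
  cur <- curvature_ratios(pair, level)
  if (anyNA(cur))
    reasons[names(cur)] <- attr(cur, "reason")
  ratios <- c(lung_volume_ratio = volume_ratio(pair),
              diaphragm_volume_ratio = as.numeric(dvr),
              ext[c("lung_area_ratio", "cranial_caudal_ratio",
                    "anterior_posterior_ratio", "cc_ap_ratio")],
              cur)
  structure(list(ratios = ratios[OUTCOME_NAMES],
                 raw = phase_raw_measures(pair, level), level = level,
                 reasons = reasons),
            class = "subject_measures")
}

# Per-phase raw values behind the ratios (mm, mm^2, mm^3).
phase_raw_measures <- function(pair, level) {
  sp <- pair$expiration$spacing
  do.call(rbind, lapply(PHASES, function(phase) {
    m <- pair[[phase]]
    sl <- m$data[level, , ]
    cc <- axis_extent(apply(sl, 2, any))
    ap <- axis_extent(apply(sl, 1, any))
    g <- dome_geometry(sl, sp[2:3])
    data.frame(
      phase = phase,
      lung_volume = sum(m$data) * voxel_volume(m),
      lung_area = sum(sl) * sp[2] * sp[3],
      cc_extent = if (is.null(cc)) NA_real_ else (cc[2] - cc[1] + 1) * sp[3],
      ap_extent = if (is.null(ap)) NA_real_ else (ap[2] - ap[1] + 1) * sp[2],
      dome_height = if (inherits(g, "dome_geometry")) g$height else NA_real_,
      dome_area = if (inherits(g, "dome_geometry")) g$area else NA_real_,
      stringsAsFactors = FALSE)
  }))
}

#' Longitudinal measurement of one subject
#'
#' Runs the full per-subject chain: selects the mid hemi-diaphragm level on
#' the initial expiratory right lung, matches it onto the follow-up visit by
#' integer-shift Dice registration of the expiratory right-lung masks,
#' computes all eight outcomes at both visits, and returns per-outcome
#' change scores (follow-up minus initial; missing values propagate).
#'
#' @param pair_initial,pair_followup [breath_pair()]s of the two visits.
#' @param window Matching search half-width in voxels.
#' @return List with `initial` and `followup` (`subject_measures`), `change`
#'   (named vector), `level_initial`, `level_followup`, and `match`
#'   diagnostics.
#' @export
compute_subject <- function(pair_initial, pair_followup, window = 10L) {
  stopifnot(inherits(pair_initial, "breath_pair"),
            inherits(pair_followup, "breath_pair"))
  sides1 <- split_sides(pair_initial$expiration)
  sides2 <- split_sides(pair_followup$expiration)
  level1 <- select_sagittal_level(sides1$right)
  m <- match_visits(sides1$right, sides2$right, level1, window = window)
  meas1 <- compute_measures(pair_initial, level = level1)
  meas2 <- compute_measures(pair_followup, level = m$level)
  list(initial = meas1, followup = meas2,
       change = meas2$ratios - meas1$ratios,
       level_initial = level1, level_followup = m$level, match = m)
}
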