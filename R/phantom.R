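# Parametric thorax phantom.
#
# Each lung is an elliptic cylinder (the chest-wall envelope) capped at the
# lung apex and floored by a diaphragm dome that bulges cranially into the
# lung base. The dome is an elliptic paraboloid by default, which gives
# closed-form values for every outcome the measurement module computes:
# cap volume pi*a*b*h/2, mid-sagittal dome height h and parabola-segment
# area (4/3)*b*h. A spherical-cap dome (circular footprint) is available as
# an alternative, with the corresponding sphere-cap and circle-segment
# closed forms. All lengths are mm.

#' Diaphragm dome specification
#'
#' @param base_level Cranio-caudal position (mm) of the dome attachment ring.
#' @param height Apex elevation h (mm) above `base_level`.
#' @param semiaxes Length-2 vector `c(a, b)`: right-left and
#'   anterior-posterior semi-axes (mm) of the elliptical dome footprint.
#' @param shape `"paraboloid"` (default) or `"spherical"` (requires
#'   `a == b`).
#' @return An object of class `dome_spec`.
#' @export
dome_spec <- function(base_level, height, semiaxes,
                      shape = c("paraboloid", "spherical")) {
  shape <- match.arg(shape)
  stopifnot(length(semiaxes) == 2L)
  if (height < 0) stop("dome height must be >= 0")
  if (any(semiaxes <= 0)) stop("dome semiaxes must be > 0")
  if (shape == "spherical" && abs(semiaxes[1] - semiaxes[2]) > 1e-9)
    stop("spherical dome requires a circular footprint (a == b)")
  structure(list(base_level = base_level, height = height,
                 semiaxes = as.numeric(semiaxes), shape = shape),
            class = "dome_spec")
}

# Elevation of the dome surface above base_level at squared normalized
# radius u = (x'/a)^2 + (y'/b)^2 (vectorized over u).
dome_elevation <- function(dome, u) {
  if (dome$height == 0) return(rep(0, length(u)))
  if (dome$shape == "paraboloid") {
    dome$height * pmax(0, 1 - u)
  } else {
    a <- dome$semiaxes[1]; h <- dome$height
    R <- (a^2 + h^2) / (2 * h)
    r2 <- pmin(u, 1) * a^2
    ifelse(u >= 1, 0, sqrt(R^2 - r2) - (R - h))
  }
}

# Closed-form volume of the dome cap.
dome_cap_volume <- function(dome) {
  a <- dome$semiaxes[1]; b <- dome$semiaxes[2]; h <- dome$height
  if (dome$shape == "paraboloid") pi * a * b * h / 2
  else pi * h * (3 * a^2 + h^2) / 6
}

# Closed-form area of the mid-sagittal dome segment (between the dome curve
# and its base chord) and the dome height on that slice.
dome_sagittal <- function(dome) {
  b <- dome$semiaxes[2]; h <- dome$height
  if (dome$shape == "paraboloid") {
    area <- 4 / 3 * b * h
  } else {
    R <- (b^2 + h^2) / (2 * h)
    area <- R^2 * acos((R - h) / R) - (R - h) * sqrt(2 * R * h - h^2)
  }
  list(height = h, area = area)
}

PHASES <- c("expiration", "inspiration")

#' Phantom geometry parameters
#'
#' Defines a two-lung voxel phantom for one visit: a shared grid, per-phase
#' chest-wall envelopes (elliptic cylinders), per-phase diaphragm domes and
#' lung apex levels. Inspiration differs from expiration by diaphragm descent
#' (lower `base_level`), optional apex rise, and optional anterior-posterior
#' chest-wall expansion (larger envelope B). The defaults describe an adult
#' thorax at the 3 mm acquisition spacing with moderately reduced diaphragm
#' motion.
#'
#' @param spacing Voxel spacing in mm (scalar or length 3).
#' @param box Physical grid extent in mm, length 3 (right-left,
#'   posterior-anterior, caudal-cranial).
#' @param lung_offset Lateral distance (mm) of each lung centre from the
#'   grid's right-left midline.
#' @param envelope Named list (`expiration`, `inspiration`) of length-2
#'   vectors `c(A, B)`: chest-wall envelope semi-axes in mm.
#' @param dome Named list (`expiration`, `inspiration`) of [dome_spec()]
#'   objects. The dome footprint must fit inside the envelope.
#' @param apex Named numeric vector (`expiration`, `inspiration`): lung apex
#'   level in mm.
#' @param ap_center Anterior-posterior position (mm) of the lung centres;
#'   defaults to the grid midline.
#' @param shift Length-3 rigid translation (mm) applied to the whole
#'   geometry in both phases (used to emulate repositioning between visits).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(spacing = 3,
                           box = c(300, 220, 260),
                           lung_offset = 75,
                           envelope = list(expiration = c(55, 70),
                                           inspiration = c(55, 88)),
                           dome = list(
                             expiration = dome_spec(80, 30, c(49, 64)),
                             inspiration = dome_spec(45, 36, c(49, 64))),
                           apex = c(expiration = 200, inspiration = 215),
                           ap_center = NULL,
                           shift = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0),
            length(box) == 3L, all(box > 0), length(shift) == 3L)
  if (is.null(ap_center)) ap_center <- box[2] / 2
  envelope <- envelope[PHASES]; dome <- dome[PHASES]; apex <- apex[PHASES]
  if (any(vapply(envelope, is.null, TRUE)) ||
      any(vapply(dome, is.null, TRUE)) || anyNA(apex))
    stop("envelope, dome and apex must each name phases ",
         paste(PHASES, collapse = " and "))
  for (ph in PHASES) {
    stopifnot(inherits(dome[[ph]], "dome_spec"),
              length(envelope[[ph]]) == 2L, all(envelope[[ph]] > 0))
    if (any(dome[[ph]]$semiaxes > envelope[[ph]] + 1e-9))
      stop("dome footprint exceeds the chest-wall envelope (", ph, ")")
    if (dome[[ph]]$base_level + dome[[ph]]$height >= apex[[ph]])
      stop("dome apex reaches the lung apex level (", ph, ")")
  }
  if (dome$inspiration$base_level > dome$expiration$base_level + 1e-9)
    stop("the diaphragm must not ascend on inspiration ",
         "(inspiration base_level > expiration base_level)")
  p <- structure(list(spacing = as.numeric(spacing), box = as.numeric(box),
                      lung_offset = lung_offset, envelope = envelope,
                      dome = dome, apex = apex, ap_center = ap_center,
                      shift = as.numeric(shift)),
                 class = "phantom_params")
  check_phantom_fits(p)
  p
}

lung_centres <- function(params) {
  cx <- params$box[1] / 2 + c(right = -1, left = 1) * params$lung_offset +
    params$shift[1]
  list(x = cx, y = params$ap_center + params$shift[2])
}

check_phantom_fits <- function(params) {
  ctr <- lung_centres(params)
  for (ph in PHASES) {
    A <- params$envelope[[ph]][1]; B <- params$envelope[[ph]][2]
    lo <- params$dome[[ph]]$base_level + params$shift[3]
    hi <- params$apex[[ph]] + params$shift[3]
    if (min(ctr$x) - A < 0 || max(ctr$x) + A > params$box[1] ||
        ctr$y - B < 0 || ctr$y + B > params$box[2] ||
        lo < 0 || hi > params$box[3])
      stop("sizing error: grid too small to contain the ", ph, " geometry")
  }
  if (params$envelope$expiration[1] >= params$lung_offset)
    stop("sizing error: lungs overlap (envelope A >= lung_offset)")
  invisible(params)
}

# Rasterize one phase: union of the two lungs on the shared grid.
rasterize_phase <- function(params, phase) {
  sp <- params$spacing
  n <- pmax(1L, ceiling(params$box / sp))
  xs <- (seq_len(n[1]) - 1) * sp[1]
  ys <- (seq_len(n[2]) - 1) * sp[2]
  zs <- (seq_len(n[3]) - 1) * sp[3]
  ctr <- lung_centres(params)
  A <- params$envelope[[phase]][1]; B <- params$envelope[[phase]][2]
  dome <- params$dome[[phase]]
  a <- dome$semiaxes[1]; b <- dome$semiaxes[2]
  base <- dome$base_level + params$shift[3]
  apex <- params$apex[[phase]] + params$shift[3]
  arr <- array(FALSE, dim = n)
  for (cx in ctr$x) {
    dx2 <- ((xs - cx) / A)^2
    dy2 <- ((ys - ctr$y) / B)^2
    env <- outer(dx2, dy2, "+") <= 1            # nx x ny envelope footprint
    u <- outer(((xs - cx) / a)^2, ((ys - ctr$y) / b)^2, "+")
    zd <- base + matrix(dome_elevation(dome, u), nrow = n[1])
    for (k in seq_len(n[3])) {
      if (zs[k] > apex) break
      hit <- env & (zs[k] > zd)
      if (any(hit)) arr[, , k] <- arr[, , k] | hit
    }
  }
  mask_volume(arr, spacing = sp)
}

#' Build a breath-hold phantom pair
#'
#' Rasterizes the expiration and inspiration phases of a phantom onto their
#' shared grid. A voxel belongs to a lung when its centre lies inside the
#' chest-wall envelope, at or below the apex level, and strictly cranial to
#' the diaphragm dome surface. The result has exactly two connected
#' components (one per lung) in each phase.
#'
#' @param params A [phantom_params()] object.
#' @return A [breath_pair()].
#' @export
build_phantom_pair <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  breath_pair(expiration = rasterize_phase(params, "expiration"),
              inspiration = rasterize_phase(params, "inspiration"))
}

#' Closed-form ground truth for a phantom
#'
#' Computes, per phase, the exact lung volume, mid-sagittal lung area,
#' cranial-caudal and anterior-posterior extents, dome height and dome area,
#' the diaphragm-swept volume between phases, and all eight outcome ratios.
#' The swept-volume closed form requires the dome footprint and shape to be
#' identical across phases and the descent to dominate any dome-height
#' increase (so the expiratory surface is nowhere below the inspiratory one).
#'
#' @param params A [phantom_params()] object.
#' @return An object of class `analytic_truth`: list with `phases` (per-phase
#'   raw values), `swept_volume`, and `ratios` (named vector over
#'   [outcome_names()]).
#' @export
analytic_truth <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  ph <- lapply(PHASES, function(phase) {
    A <- params$envelope[[phase]][1]; B <- params$envelope[[phase]][2]
    dome <- params$dome[[phase]]
    cc <- params$apex[[phase]] - dome$base_level
    sag <- dome_sagittal(dome)
    list(lung_volume = 2 * (pi * A * B * cc - dome_cap_volume(dome)),
         cc_extent = cc,
         ap_extent = 2 * B,
         lung_area = 2 * B * cc - sag$area,
         dome_height = sag$height,
         dome_area = sag$area)
  })
  names(ph) <- PHASES
  e <- params$dome$expiration; i <- params$dome$inspiration
  descent <- e$base_level - i$base_level
  swept <- NA_real_
  if (isTRUE(all.equal(e$semiaxes, i$semiaxes)) && e$shape == i$shape &&
      descent + min(0, e$height - i$height) >= -1e-9 &&
      all(params$envelope$inspiration >= params$envelope$expiration - 1e-9)) {
    Ae <- params$envelope$expiration[1]; Be <- params$envelope$expiration[2]
    swept <- 2 * (descent * pi * Ae * Be +
                    dome_cap_volume(e) - dome_cap_volume(i))
  }
  vgain <- ph$inspiration$lung_volume - ph$expiration$lung_volume
  ratios <- c(
    lung_volume_ratio = ph$inspiration$lung_volume / ph$expiration$lung_volume,
    diaphragm_volume_ratio = if (vgain > 0) swept / vgain else NA_real_,
    lung_area_ratio = ph$inspiration$lung_area / ph$expiration$lung_area,
    cranial_caudal_ratio = ph$inspiration$cc_extent / ph$expiration$cc_extent,
    anterior_posterior_ratio =
      ph$inspiration$ap_extent / ph$expiration$ap_extent,
    cc_ap_ratio = NA_real_,
    diaphragm_height_ratio =
      if (ph$expiration$dome_height > 0)
        ph$inspiration$dome_height / ph$expiration$dome_height else NA_real_,
    diaphragm_area_ratio =
      if (ph$expiration$dome_area > 0)
        ph$inspiration$dome_area / ph$expiration$dome_area else NA_real_)
  ratios["cc_ap_ratio"] <- ratios["cranial_caudal_ratio"] /
    ratios["anterior_posterior_ratio"]
  structure(list(phases = ph, swept_volume = swept, ratios = ratios),
            class = "analytic_truth")
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render grayscale volumes from a mask pair
#'
#' Produces simple synthetic intensity volumes to exercise the segmentation
#' stage: lung voxels dark (0.15), body bright (0.85), plus additive Gaussian
#' noise. No MR physics is simulated.
#'
#' @param pair A [breath_pair()].
#' @param noise_scale Standard deviation of the additive noise (>= 0).
#' @param seed Optional integer; when given the output is reproducible.
#' @return Named list (`expiration`, `inspiration`) of lists with `data`
#'   (numeric 3D array) and `spacing`.
#' @export
render_intensity <- function(pair, noise_scale = 0.1, seed = NULL) {
  stopifnot(inherits(pair, "breath_pair"), noise_scale >= 0)
  with_seed(seed, {
    lapply(stats::setNames(PHASES, PHASES), function(phase) {
      m <- pair[[phase]]
      img <- array(0.85, dim = dim(m$data))
      img[m$data] <- 0.15
      if (noise_scale > 0)
        img <- img + array(rnorm(length(img), sd = noise_scale),
                           dim = dim(img))
      list(data = img, spacing = m$spacing)
    })
  })
}

#' Randomized phantom within plausible ranges
#'
#' Draws a compact-thorax phantom (from the current RNG state) whose
#' geometry admits closed-form truth for all eight outcomes: shared dome
#' footprint across phases, diaphragm descent dominating any dome-height
#' increase, and nested chest-wall envelopes. Intended for oracle-equivalence
#' studies at fine spacing; all outcome ratios are scale-free.
#'
#' @param spacing Voxel spacing in mm (scalar or length 3).
#' @return A [phantom_params()] object.
#' @export
random_phantom_params <- function(spacing = 1) {
  A <- runif(1, 32, 42)
  B_e <- runif(1, 40, 52)
  B_i <- B_e * runif(1, 1.1, 1.35)
  a <- A - 4
  b <- B_e - 4
  h_e <- runif(1, 16, 24)
  h_i <- runif(1, 0.7, 1.6) * h_e
  base_e <- runif(1, 32, 40)
  d <- runif(1, max(16, h_i - h_e + 3), 30)
  cc0 <- runif(1, 55, 75)
  apex_e <- base_e + cc0
  apex_i <- apex_e + runif(1, 4, 10)
  lung_offset <- A + 8
  box <- c(2 * (lung_offset + A) + 10, 2 * B_i + 14, apex_i + 8)
  phantom_params(
    spacing = spacing, box = box, lung_offset = lung_offset,
    envelope = list(expiration = c(A, B_e), inspiration = c(A, B_i)),
    dome = list(expiration = dome_spec(base_e, h_e, c(a, b)),
                inspiration = dome_spec(base_e - d, h_i, c(a, b))),
    apex = c(expiration = apex_e, inspiration = apex_i),
    ap_center = box[2] / 2)
}
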