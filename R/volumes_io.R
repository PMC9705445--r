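# Mask volumes, breath pairs, and file I/O.
#
# One axis convention holds throughout the package and is enforced at load
# time: axis 1 runs subject right -> left, axis 2 posterior -> anterior,
# axis 3 caudal -> cranial ("LAS" in NIfTI orientation terms). Voxel centres
# sit at physical coordinate (index - 1) * spacing along each axis, in mm.

AXIS_CONVENTION <- "LAS"

#' Construct a mask volume
#'
#' A `mask_volume` is a 3D logical voxel grid with per-axis spacing in mm and
#' the package's fixed anatomical axis convention (right->left,
#' posterior->anterior, caudal->cranial).
#'
#' @param data 3D array; coerced to logical (`> 0` for numeric input).
#' @param spacing Voxel spacing in mm: scalar (isotropic) or length-3 vector.
#' @return An object of class `mask_volume` with elements `data` (logical 3D
#'   array), `spacing` (numeric length 3) and `axes` (orientation tag).
#' @export
mask_volume <- function(data, spacing = 3) {
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  if (is.numeric(data)) data <- data > 0
  if (!is.logical(data)) stop("mask data must be logical or numeric")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 1 or 3 positive values (mm)")
  if (any(dim(data) < 1L)) stop("mask grid is empty")
  structure(list(data = data, spacing = spacing, axes = AXIS_CONVENTION),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s voxels @ %s mm (%s), %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              x$axes, sum(x$data)))
  invisible(x)
}

#' @export
dim.mask_volume <- function(x) dim(x$data)

voxel_volume <- function(mask) prod(mask$spacing)

#' Pair of breath-hold masks for one visit
#'
#' Binds the end-expiration and end-inspiration masks of one scanning session.
#' Both phases are acquired in the same scanner frame and must share grid
#' shape and spacing.
#'
#' @param expiration,inspiration `mask_volume` objects on a common grid.
#' @return An object of class `breath_pair`.
#' @export
breath_pair <- function(expiration, inspiration) {
  stopifnot(inherits(expiration, "mask_volume"),
            inherits(inspiration, "mask_volume"))
  if (!identical(dim(expiration$data), dim(inspiration$data)))
    stop("expiration and inspiration grids differ in shape")
  if (!isTRUE(all.equal(expiration$spacing, inspiration$spacing)))
    stop("expiration and inspiration grids differ in spacing")
  structure(list(expiration = expiration, inspiration = inspiration),
            class = "breath_pair")
}

#' @export
print.breath_pair <- function(x, ...) {
  cat("<breath_pair>\n  expiration: "); print(x$expiration)
  cat("  inspiration: "); print(x$inspiration)
  invisible(x)
}

# xform matrix placing voxel (1,1,1) at the origin under the package
# convention; first physical axis points subject-left, hence the LAS letters.
las_xform <- function(spacing) {
  m <- diag(c(-spacing[1], spacing[2], spacing[3], 1))
  structure(m, code = 2L)
}

#' Write a mask volume as NIfTI-1
#'
#' Voxel values are 0/1, spacing is written to `pixdim`, and the sform/qform
#' encode the package's axis convention so that third-party tools (and
#' [load_mask()]) can recover the orientation.
#'
#' @param mask A `mask_volume`.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::qform(img) <- las_xform(mask$spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Load a lung mask from NIfTI
#'
#' Reads a 3D single-channel volume, binarizes it at `> 0` (multi-label
#' per-lung inputs, e.g. left = 1 / right = 2, are accepted; the label values
#' present are recorded in the `labels` attribute), takes spacing from the
#' header, and reorients the grid to the package convention using the
#' qform/sform. Files without orientation metadata are assumed to already
#' follow the convention.
#'
#' @param path NIfTI file path.
#' @return A `mask_volume`.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { dim(img) <- d[1:3]; d <- dim(img) }
  if (length(d) != 3L)
    stop("load error: expected a 3D single-channel volume, got dims [",
         paste(d, collapse = ", "), "]")
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0L || hdr$sform_code > 0L) {
    ori <- RNifti::orientation(img)
    if (is.na(ori) || !nzchar(ori))
      stop("load error: unrecognized orientation metadata")
    if (ori != AXIS_CONVENTION) RNifti::orientation(img) <- AXIS_CONVENTION
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("load error: missing or non-positive spacing in header field pixdim")
  arr <- as.array(img)
  labels <- sort(unique(as.vector(arr[arr > 0])))
  out <- mask_volume(arr > 0, spacing = spacing)
  attr(out, "labels") <- labels
  out
}

COHORT_COLUMNS <- c("id", "group", "sex", "age_years", "height_cm",
                    "weight_kg", "ert_status", "ert_duration_years",
                    "followup_years")

#' Load a per-subject cohort table
#'
#' Reads the demographic/clinical table: one row per subject with `id`,
#' `group` (patient|control, case-insensitive), `sex` (M|F), `age_years`,
#' `height_cm`, `weight_kg`, `ert_status` (untreated|treated; empty for
#' controls), `ert_duration_years` (years of enzyme replacement therapy at
#' the initial MRI; may be empty for untreated patients) and
#' `followup_years`. Extra columns are kept. A validation report of missing
#' optional fields is attached as attribute `"validation"`.
#'
#' @param path CSV file (UTF-8, header row, decimal point).
#' @return A data.frame of class `cohort_table`.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "group")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort table is missing required column(s): ",
         paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate subject id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  df$group <- tolower(trimws(df$group))
  bad <- setdiff(unique(df$group), c("patient", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected patient or control)")
  if (!"ert_status" %in% names(df)) df$ert_status <- NA_character_
  if (!"ert_duration_years" %in% names(df))
    df$ert_duration_years <- NA_real_
  df$ert_status <- tolower(trimws(as.character(df$ert_status)))
  df$ert_status[df$ert_status %in% c("", "na")] <- NA_character_
  # untreated patients legitimately have no duration; flag rather than drop
  untreated <- !is.na(df$ert_status) & df$ert_status == "untreated"
  if (any(!is.na(df$ert_status[df$group == "control"])))
    warning("ERT status present for controls; ignored")
  df$ert_status[df$group == "control"] <- NA_character_
  df$ert_duration_years[df$group == "control"] <- NA_real_
  report <- character(0)
  for (col in setdiff(COHORT_COLUMNS, c("id", "group"))) {
    if (!col %in% names(df)) report <- c(report, paste0("column absent: ", col))
    else if (anyNA(df[[col]]) && col != "ert_duration_years" &&
             col != "ert_status")
      report <- c(report, paste0("missing values in: ", col))
  }
  if (any(untreated))
    report <- c(report, paste0(sum(untreated), " untreated patient(s)"))
  attr(df, "validation") <- report
  class(df) <- c("cohort_table", "data.frame")
  df
}

VISIT_LEVELS <- c("initial", "follow-up")

#' Load a per-subject outcomes table
#'
#' Reads a long-format CSV with one row per subject and visit carrying the
#' eight MRI outcome ratios (see [outcome_names()]) and, optionally,
#' pulmonary-function values in percent predicted (`fvc_upright`,
#' `fvc_supine`, `mip`, `mep`). This is the entry point for an externally
#' measured per-subject table (for instance a study supplement converted to
#' CSV), so downstream statistics can run without recomputing from images.
#' Required columns: `id`, `group`, `visit` (initial|follow-up; the spelling
#' `followup` is normalised), and all eight outcomes. Extra columns are
#' tolerated and kept.
#'
#' @param path CSV file path.
#' @return A data.frame of class `outcomes_table`.
#' @export
load_supplementary_outcomes <- function(path) {
  if (!file.exists(path)) stop("outcomes file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "visit", OUTCOME_NAMES)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("outcomes table is missing expected column(s): ",
         paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df$group <- tolower(trimws(df$group))
  bad <- setdiff(unique(df$group), c("patient", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df$visit <- tolower(trimws(df$visit))
  df$visit[df$visit %in% c("followup", "follow_up")] <- "follow-up"
  badv <- setdiff(unique(df$visit), VISIT_LEVELS)
  if (length(badv))
    stop("unknown visit label(s): ", paste(badv, collapse = ", "),
         " (expected initial or follow-up)")
  if (anyDuplicated(df[c("id", "visit")]))
    stop("duplicate (id, visit) row(s) in outcomes table")
  for (col in OUTCOME_NAMES) df[[col]] <- as.numeric(df[[col]])
  class(df) <- c("outcomes_table", "data.frame")
  df
}

#' Print the CSV schemas used by the package
#'
#' @return Invisibly, a list with the two column inventories.
#' @export
table_schemas <- function() {
  cat("cohort table columns:\n  ", paste(COHORT_COLUMNS, collapse = ", "),
      "\n  group: patient|control; ert_status: untreated|treated (patients",
      "only)\n")
  cat("outcomes table columns:\n  id, group, visit,",
      paste(OUTCOME_NAMES, collapse = ", "),
      "\n  [optional] fvc_upright, fvc_supine, mip, mep",
      "\n  visit: initial|follow-up; extra columns are kept\n")
  invisible(list(cohort = COHORT_COLUMNS,
                 outcomes = c("id", "group", "visit", OUTCOME_NAMES)))
}
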