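# Reference segmenter for synthetic intensity volumes.
#
# Real anatomical lung segmentation (e.g. a trained CNN) is out of scope;
# externally produced masks enter through load_mask(). This module provides
# the minimal chain needed to close the loop on phantom renderings:
# threshold, keep the two largest 26-connected components, fill internal
# cavities, and split the result into right/left lungs.

label_components <- function(arr, connectivity = 26L) {
  .label_components_cpp(as.logical(arr), as.integer(dim(arr)),
                        as.integer(connectivity))
}

# Fill 3D internal cavities: background regions (6-connectivity) that do not
# touch the grid border become foreground.
fill_cavities <- function(arr) {
  bg <- label_components(!arr, connectivity = 6L)
  d <- dim(arr)
  border <- setdiff(unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                             bg[, , c(1, d[3])])), 0L)
  cavity <- !arr & !array(bg %in% border, dim = d)
  arr | cavity
}

# Otsu's histogram threshold: maximises the between-class variance of the
# two-class split. Returns a threshold value on the intensity scale.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite intensities")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(x, breaks, all.inside = TRUE), nbins))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[nbins]; tot_mu <- mu[nbins]
  w1 <- w[-nbins]; w2 <- tot_w - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (tot_mu * w1[valid] - tot_w * mu[-nbins][valid])^2 /
    (w1[valid] * w2[valid])
  breaks[which.max(bcv) + 1L]
}

#' Segment lungs from a grayscale volume
#'
#' Thresholds the volume (lungs are dark), keeps the two largest 26-connected
#' components above a minimum size, and fills internal cavities. The
#' threshold is Otsu's by default; pass a fixed value to override.
#'
#' @param intensity A 3D numeric array, or a list with elements `data` and
#'   `spacing` as returned by [render_intensity()].
#' @param threshold `"otsu"` (default) or a fixed numeric cutoff; voxels with
#'   intensity strictly below it are lung candidates.
#' @param spacing Voxel spacing in mm when `intensity` is a bare array.
#' @param min_size_frac Minimum component size as a fraction of grid voxels
#'   (default 0.01).
#' @return A `mask_volume` containing both lungs.
#' @export
segment_lungs <- function(intensity, threshold = "otsu", spacing = 3,
                          min_size_frac = 0.01) {
  if (is.list(intensity)) {
    spacing <- intensity$spacing
    intensity <- intensity$data
  }
  if (length(dim(intensity)) != 3L)
    stop("intensity must be a 3D volume")
  thr <- if (identical(threshold, "otsu")) otsu_threshold(intensity)
         else as.numeric(threshold)
  cand <- intensity < thr
  lab <- label_components(cand, connectivity = 26L)
  sizes <- tabulate(lab)
  min_size <- max(1, ceiling(min_size_frac * length(cand)))
  big <- which(sizes >= min_size)
  if (length(big) < 2L)
    stop("segmentation failure: fewer than two components above ",
         "minimum size (", min_size, " voxels)")
  keep <- big[order(sizes[big], decreasing = TRUE)][1:2]
  out <- array(lab %in% keep, dim = dim(cand))
  out <- fill_cavities(out)
  mask_volume(out, spacing = spacing)
}

#' Split a two-lung mask into right and left lungs
#'
#' Requires exactly two 26-connected components; assigns sides by the mean
#' coordinate along axis 1, which runs subject right to left (the right lung
#' has the smaller mean index).
#'
#' @param mask A `mask_volume` with exactly two connected components.
#' @return An object of class `lung_pair`: list with `right` and `left`
#'   `mask_volume`s that partition the input.
#' @export
split_sides <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  lab <- label_components(mask$data, connectivity = 26L)
  k <- max(lab)
  if (k != 2L)
    stop("expected exactly two connected components, found ", k,
         if (k == 1L) " (merged lungs; erosion-based splitting is not attempted)"
         else "")
  idx <- which(mask$data, arr.ind = TRUE)
  mean_x <- tapply(idx[, 1], lab[mask$data], mean)
  right_label <- as.integer(names(which.min(mean_x)))
  right <- mask_volume(array(lab == right_label, dim = dim(mask$data)),
                       spacing = mask$spacing)
  left <- mask_volume(array(lab == (3L - right_label), dim = dim(mask$data)),
                      spacing = mask$spacing)
  structure(list(right = right, left = left), class = "lung_pair")
}
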