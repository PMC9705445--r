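# Shared fixture builders. Everything is generated in code at test time.

# Randomized oracle phantoms come from the package generator.
random_phantom <- function(spacing = 1) random_phantom_params(spacing)

# Compact default-style phantom for fast unit tests at 3 mm.
small_phantom <- function(spacing = 3, ...) {
  phantom_params(
    spacing = spacing,
    box = c(190, 120, 130),
    lung_offset = 48,
    envelope = list(expiration = c(38, 46), inspiration = c(38, 54)),
    dome = list(expiration = dome_spec(36, 20, c(34, 42)),
                inspiration = dome_spec(14, 16, c(34, 42))),
    apex = c(expiration = 110, inspiration = 120),
    ...)
}

# Rigid chest wall, descent-only: identical envelope, dome shape and apex
# in both phases; the diaphragm sweeps the entire volume gain.
descent_only_phantom <- function(spacing = 3, descent = 22) {
  phantom_params(
    spacing = spacing,
    box = c(190, 120, 130),
    lung_offset = 48,
    envelope = list(expiration = c(38, 46), inspiration = c(38, 46)),
    dome = list(expiration = dome_spec(40, 20, c(34, 42)),
                inspiration = dome_spec(40 - descent, 20, c(34, 42))),
    apex = c(expiration = 110, inspiration = 110))
}

translate_mask <- function(mask, shift) {
  d <- dim(mask$data)
  out <- array(FALSE, dim = d)
  src <- lapply(1:3, function(ax) {
    s <- shift[ax]
    list(from = max(1, 1 - s):min(d[ax], d[ax] - s))
  })
  idx_to <- lapply(1:3, function(ax) src[[ax]]$from + shift[ax])
  out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
    mask$data[src[[1]]$from, src[[2]]$from, src[[3]]$from]
  mask_volume(out, spacing = mask$spacing)
}

translate_pair <- function(pair, shift) {
  breath_pair(translate_mask(pair$expiration, shift),
              translate_mask(pair$inspiration, shift))
}
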