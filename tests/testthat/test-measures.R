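test_that("lung volume is voxel count times voxel volume", {
  arr <- array(FALSE, dim = c(14, 14, 14))
  arr[3:12, 3:12, 3:12] <- TRUE
  expect_equal(lung_volume(mask_volume(arr, spacing = 3)), 27000)
  expect_error(lung_volume(mask_volume(array(FALSE, c(4, 4, 4)))), "empty")
})

test_that("identical phases give unit ratios and an undefined volume fraction", {
  m <- build_phantom_pair(small_phantom())$expiration
  pair <- breath_pair(m, m)
  res <- compute_measures(pair)
  defined <- setdiff(outcome_names(), "diaphragm_volume_ratio")
  expect_equal(unname(res$ratios[defined]), rep(1, 7))
  expect_true(is.na(res$ratios["diaphragm_volume_ratio"]))
  expect_match(res$reasons$diaphragm_volume_ratio, "volume gain")
})

test_that("diaphragm surface matches the generator dome within one voxel", {
  p <- small_phantom(spacing = 2)
  pair <- build_phantom_pair(p)
  m <- pair$expiration
  surf <- diaphragm_surface(m)
  sp <- m$spacing
  dome <- p$dome$expiration
  ctr_x <- p$box[1] / 2 + c(-1, 1) * p$lung_offset
  cols <- which(!is.na(surf), arr.ind = TRUE)
  expect_gt(nrow(cols), 100)
  for (r in sample(nrow(cols), 50)) {
    i <- cols[r, 1]; j <- cols[r, 2]
    x <- (i - 1) * sp[1]; y <- (j - 1) * sp[2]
    cx <- ctr_x[which.min(abs(ctr_x - x))]
    u <- ((x - cx) / dome$semiaxes[1])^2 +
      ((y - p$ap_center) / dome$semiaxes[2])^2
    zd <- dome$base_level + dome$height * max(0, 1 - u)
    z_meas <- (surf[i, j] - 1) * sp[3]
    expect_lt(z_meas - zd, sp[3] + 1e-9)
    expect_gte(z_meas - zd, 0)
  }
  # a solid block has a flat surface at its lowest index
  arr <- array(FALSE, dim = c(8, 8, 8)); arr[2:7, 2:7, 4:7] <- TRUE
  s <- diaphragm_surface(mask_volume(arr))
  expect_true(all(s[2:7, 2:7] == 4L))
  expect_true(all(is.na(s[1, ])))
})

test_that("descent-only phantom yields diaphragm volume ratio 1", {
  pair <- build_phantom_pair(descent_only_phantom())
  expect_equal(diaphragm_volume_ratio(pair), 1, tolerance = 0.03)
})

test_that("wall-driven volume gain lowers the diaphragm volume fraction", {
  # half of the gain from AP chest-wall expansion -> ratio near 0.5
  A <- 38; B_e <- 46; dome_h <- 20; a <- 34; b <- 42
  cc0 <- 70; base_e <- 40
  d <- 20
  # volume gain = pi*A*[B_i*(cc0+d) - B_e*cc0]; the diaphragm sweeps
  # pi*A*B_e*d, so B_i below makes the wall contribute exactly as much
  B_i <- B_e * (cc0 + 2 * d) / (cc0 + d)
  p <- phantom_params(
    spacing = 1.5, box = c(190, 130, 130), lung_offset = 48,
    envelope = list(expiration = c(A, B_e), inspiration = c(A, B_i)),
    dome = list(expiration = dome_spec(base_e, dome_h, c(a, b)),
                inspiration = dome_spec(base_e - d, dome_h, c(a, b))),
    apex = c(expiration = base_e + cc0, inspiration = base_e + cc0))
  truth <- analytic_truth(p)$ratios[["diaphragm_volume_ratio"]]
  expect_equal(truth, 0.5, tolerance = 0.01)
  expect_equal(diaphragm_volume_ratio(build_phantom_pair(p)), truth,
               tolerance = 0.03)
})

test_that("sagittal level selection is the right-lung midpoint and equivariant", {
  arr <- array(FALSE, dim = c(40, 10, 10))
  arr[11:31, 2:9, 2:9] <- TRUE
  expect_equal(select_sagittal_level(mask_volume(arr)), 21L)
  pair <- build_phantom_pair(small_phantom())
  sides <- split_sides(pair$expiration)
  lev <- select_sagittal_level(sides$right)
  shifted <- translate_mask(sides$right, c(5, 0, 0))
  expect_equal(select_sagittal_level(shifted), lev + 5L)
  # the selected slice passes within one voxel of the dome apex column
  p <- small_phantom()
  cx_right <- (p$box[1] / 2 - p$lung_offset) / p$spacing[1] + 1
  expect_lt(abs(lev - cx_right), 1 + 1e-9)
})

test_that("visit matching recovers pure translations exactly", {
  sides <- split_sides(build_phantom_pair(small_phantom())$expiration)
  lev <- select_sagittal_level(sides$right)
  m0 <- match_visits(sides$right, sides$right, lev)
  expect_equal(m0$shift, c(0L, 0L, 0L))
  expect_equal(m0$dice, 1)
  shifted <- translate_mask(sides$right, c(3, -2, 4))
  m <- match_visits(sides$right, shifted, lev)
  expect_equal(m$shift, c(3L, -2L, 4L))
  expect_equal(m$dice, 1)
  expect_equal(m$level, lev + 3L)
  expect_false(m$fallback)
})

test_that("visit matching tolerates shape change and warns when hopeless", {
  p1 <- small_phantom()
  p2 <- small_phantom(shift = c(6, -3, 3))
  p2$dome$expiration$height <- p2$dome$expiration$height + 2  # mild change
  s1 <- split_sides(build_phantom_pair(p1)$expiration)$right
  s2 <- split_sides(build_phantom_pair(p2)$expiration)$right
  lev <- select_sagittal_level(s1)
  m <- match_visits(s1, s2, lev)
  expect_equal(m$shift[1], 2L)  # 6 mm at 3 mm spacing
  expect_false(m$fallback)
  # disjoint masks: best Dice below 0.5 -> warning + fallback level
  far <- translate_mask(s1, c(0, 0, 30))
  expect_warning(mf <- match_visits(s1, far, lev, window = 4L),
                 "unreliable")
  expect_true(mf$fallback)
  expect_equal(mf$level, select_sagittal_level(far))
})

test_that("slice extents scale as constructed and ratios follow", {
  # stretch the expiratory slice caudally by 1.5 at fixed AP extent
  arr_e <- array(FALSE, dim = c(9, 30, 60))
  arr_i <- array(FALSE, dim = c(9, 30, 60))
  arr_e[4:6, 6:25, 11:30] <- TRUE   # 20 voxels CC
  arr_i[4:6, 6:25, 11:40] <- TRUE   # 30 voxels CC
  pair <- breath_pair(mask_volume(arr_e), mask_volume(arr_i))
  r <- slice_extent_ratios(pair, 5L)
  expect_equal(unname(r["cranial_caudal_ratio"]), 1.5)
  expect_equal(unname(r["anterior_posterior_ratio"]), 1)
  expect_equal(unname(r["cc_ap_ratio"]), 1.5)
  expect_equal(unname(r["lung_area_ratio"]), 1.5)
  # empty slice -> undefined with reason
  r2 <- slice_extent_ratios(pair, 1L)
  expect_true(all(is.na(r2)))
  expect_match(attr(r2, "reason"), "empty")
})

test_that("dome geometry recovers closed-form shapes on fine slices", {
  # semicircular dome of radius r: height -> r, area -> pi r^2 / 2
  r <- 30; s <- 0.5
  ny <- as.integer(2 * (r + 6) / s); nz <- as.integer((r + 40) / s)
  ys <- (seq_len(ny) - 1) * s - (r + 6)
  zs <- (seq_len(nz) - 1) * s
  zd <- ifelse(abs(ys) <= r, sqrt(pmax(0, r^2 - ys^2)), 0)
  slice <- outer(seq_len(ny), seq_len(nz),
                 function(j, k) zs[k] > zd[j] & abs(ys[j]) <= r + 4 &
                   zs[k] <= r + 35)
  g <- dome_geometry(slice, c(s, s))
  expect_equal(g$height, r, tolerance = 0.03)
  expect_equal(g$area, pi * r^2 / 2, tolerance = 0.03)
  # flat diaphragm: zero height and area
  flat <- matrix(FALSE, 40, 40); flat[5:35, 10:30] <- TRUE
  gf <- dome_geometry(flat, c(1, 1))
  expect_equal(gf$height, 0)
  expect_equal(gf$area, 0)
  # paraboloid mid-slice: height h, area (4/3) b h
  p <- small_phantom(spacing = 1)
  pair <- build_phantom_pair(p)
  lev <- select_sagittal_level(split_sides(pair$expiration)$right)
  ge <- dome_geometry(pair$expiration$data[lev, , ], c(1, 1))
  h <- p$dome$expiration$height; b <- p$dome$expiration$semiaxes[2]
  expect_equal(ge$height, h, tolerance = 0.03)
  # contour and chord are each one-voxel localized: one-voxel-band slack
  expect_lt(abs(ge$area - 4 / 3 * b * h), 0.03 * 4 / 3 * b * h + 2 * b * 1)
  # fewer than 3 contour points: undefined
  tiny <- matrix(FALSE, 5, 5); tiny[2, 2] <- TRUE; tiny[3, 3] <- TRUE
  gt <- dome_geometry(tiny, c(1, 1))
  expect_true(!inherits(gt, "dome_geometry") && is.na(gt))
  expect_match(attr(gt, "reason"), "fewer than 3")
})

test_that("curvature ratios are undefined for a flat expiratory dome", {
  arr_e <- array(FALSE, dim = c(9, 30, 40)); arr_e[4:6, 6:25, 11:30] <- TRUE
  arr_i <- array(FALSE, dim = c(9, 30, 40)); arr_i[4:6, 6:25, 6:30] <- TRUE
  pair <- breath_pair(mask_volume(arr_e), mask_volume(arr_i))
  r <- curvature_ratios(pair, 5L)
  expect_true(all(is.na(r)))
  expect_match(attr(r, "reason"), "flatter than one voxel")
})

test_that("height ratio increases strictly with inspiratory dome height", {
  heights <- c(12, 16, 20, 24)
  vals <- vapply(heights, function(h) {
    p <- phantom_params(
      spacing = 2, box = c(190, 120, 130), lung_offset = 48,
      envelope = list(expiration = c(38, 46), inspiration = c(38, 46)),
      dome = list(expiration = dome_spec(36, 16, c(34, 42)),
                  inspiration = dome_spec(14, h, c(34, 42))),
      apex = c(expiration = 110, inspiration = 110))
    pair <- build_phantom_pair(p)
    lev <- select_sagittal_level(split_sides(pair$expiration)$right)
    unname(curvature_ratios(pair, lev)["diaphragm_height_ratio"])
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("all outcomes are invariant under integer translation of both phases", {
  p <- small_phantom()
  pair <- build_phantom_pair(p)
  res <- compute_measures(pair)
  moved <- translate_pair(pair, c(2, -2, 2))
  res_m <- compute_measures(moved)
  expect_equal(res_m$ratios, res$ratios)
})

test_that("subject-level chain: identical visits give zero change despite translation", {
  p <- small_phantom()
  pair <- build_phantom_pair(p)
  res0 <- compute_subject(pair, pair)
  expect_equal(unname(res0$change[!is.na(res0$change)]),
               rep(0, sum(!is.na(res0$change))))
  moved <- translate_pair(pair, c(3, 2, -2))
  res <- compute_subject(pair, moved)
  expect_equal(res$match$shift, c(3L, 2L, -2L))
  expect_equal(unname(res$change[!is.na(res$change)]),
               rep(0, sum(!is.na(res$change))))
})

test_that("swept volume never exceeds the lung volume gain under a rigid wall", {
  set.seed(19)
  for (i in 1:5) {
    d <- runif(1, 10, 26)
    h_e <- runif(1, 14, 22); h_i <- runif(1, 0.8, 1.2) * h_e
    p <- phantom_params(
      spacing = 3, box = c(190, 120, 130), lung_offset = 48,
      envelope = list(expiration = c(38, 46), inspiration = c(38, 46)),
      dome = list(expiration = dome_spec(40, h_e, c(34, 42)),
                  inspiration = dome_spec(40 - d, h_i, c(34, 42))),
      apex = c(expiration = 110, inspiration = 110))
    pair <- build_phantom_pair(p)
    gain <- lung_volume(pair$inspiration) - lung_volume(pair$expiration)
    dvr <- diaphragm_volume_ratio(pair)
    expect_lt(dvr, 1 + 0.03)
    expect_equal(dvr, 1, tolerance = 0.05)
  }
})
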