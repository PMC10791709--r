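mk_track <- function(scores, sides = "right") {
  n <- length(scores)
  new_slice_track(
    tibble::tibble(side = rep_len(sides, n),
                   slice_index = seq_len(n) - 1L, label = scores),
    scale = "ten_degree")
}
mk_areas <- function(areas, sides = "right") {
  tibble::tibble(side = rep_len(sides, length(areas)),
                 slice_index = seq_along(areas) - 1L, area_mm2 = areas)
}

test_that("SWES is the area-weighted mean of slice scores", {
  expect_equal(compute_swes(mk_track(c(1, 9)), mk_areas(c(10, 30))), 7)
  expect_equal(compute_swes(mk_track(c(0, 10)), mk_areas(c(5, 5))), 5)
  # constant scores give SWES = s for any areas
  expect_equal(compute_swes(mk_track(rep(3.3, 4)),
                            mk_areas(c(1, 10, 100, 7))), 3.3)
  expect_error(compute_swes(mk_track(c(1, 2)), mk_areas(c(0, 0))),
               "zero")
  expect_error(compute_swes(mk_track(c(1, 2)), mk_areas(3)), "matching")
})

test_that("SWES respects convexity bounds and area-rescaling invariance", {
  with_seed_test(31, {
    for (i in 1:1000) {
      n <- sample(2:40, 1)
      scores <- runif(n, 0, 10)
      areas <- runif(n, 0.1, 50)
      tr <- mk_track(scores, sides = sample(c("right", "left"), n, TRUE))
      ar <- mk_areas(areas, sides = tr$side)
      s <- compute_swes(tr, ar)
      expect_gte(s, min(scores) - 1e-12)
      expect_lte(s, max(scores) + 1e-12)
      ar2 <- ar; ar2$area_mm2 <- ar2$area_mm2 * 7.3
      expect_equal(compute_swes(tr, ar2), s)
    }
  })
})

test_that("pooled and per-lung SWES aggregation differ as documented", {
  tr <- mk_track(c(0, 10), sides = c("right", "left"))
  ar <- mk_areas(c(10, 30), sides = c("right", "left"))
  expect_equal(compute_swes(tr, ar), 7.5)               # pooled
  expect_equal(compute_swes(tr, ar, per_lung = TRUE), 5)  # mean of lung means
})

test_that("LAV950 counts voxels strictly below the threshold", {
  mk_vol <- function(hu) ct_volume(array(hu, c(5, 2, 1)), c(1, 1, 1))
  full_mask <- lung_mask(array(1L, c(5, 2, 1)), c(1, 1, 1))
  expect_equal(compute_lav950(mk_vol(-1000), full_mask), 1)
  expect_equal(compute_lav950(mk_vol(-850), full_mask), 0)
  hu <- array(-850, c(5, 2, 1)); hu[1:3] <- -960
  expect_equal(compute_lav950(ct_volume(hu, c(1, 1, 1)), full_mask), 0.3)
  # boundary: exactly -950 is not below -950
  hu[1:3] <- -950
  expect_equal(compute_lav950(ct_volume(hu, c(1, 1, 1)), full_mask), 0)
  empty <- lung_mask(array(0L, c(5, 2, 1)), c(1, 1, 1))
  expect_error(compute_lav950(mk_vol(-850), empty), "no lung")
})

test_that("LAV950 is monotone in its threshold", {
  ph <- generate_phantom(small_spec(severity = 5, seed = 17))
  thresholds <- c(-1000, -950, -900, -850)
  fracs <- vapply(thresholds, function(t)
    compute_lav950(ph$volume, ph$mask, threshold_hu = t), 0)
  expect_true(all(diff(fracs) >= 0))
})

test_that("patient flags use strict inequalities at both cutoffs", {
  rec <- tibble::tibble(sum_visual = c(2L, 3L, 0L),
                        fev1_fvc = c(0.7, 0.55, 0.71))
  out <- label_patients(rec)
  expect_equal(out$significant_emphysema, c(FALSE, TRUE, FALSE))
  expect_equal(out$obstructed, c(FALSE, TRUE, FALSE))
})

test_that("zero-angle rotation reproduces the SWES exactly", {
  fix <- trained_fixture()
  ph <- fix$test_phantoms[[2]]
  rep0 <- rotation_repeatability(ph$volume, fix$model, max_angle_deg = 0,
                                 n_rotations = 3, seed = 2)
  expect_equal(rep0$pairs$swes_rotated, rep0$pairs$swes_original)
  expect_equal(rep0$bland_altman$loa_low, rep0$bland_altman$loa_high)
  expect_equal(rep0$bland_altman$bias, 0)
})

test_that("rotation repeatability is seed-reproducible and complete", {
  fix <- trained_fixture()
  # taller phantom: a +/-7.5 degree rotation must not sweep the apices out
  # of the field of view
  ph <- generate_phantom(
    phantom_spec(grid_shape = c(40, 40, 24), spacing_mm = c(6, 6, 6),
                 severity_profile = 4, seed = 23))
  r1 <- rotation_repeatability(ph$volume, fix$model, max_angle_deg = 7.5,
                               n_rotations = 4, seed = 21)
  r2 <- rotation_repeatability(ph$volume, fix$model, max_angle_deg = 7.5,
                               n_rotations = 4, seed = 21)
  expect_identical(r1$pairs, r2$pairs)
  expect_equal(nrow(r1$pairs) + r1$n_skipped, 4)
  # the score survives small rigid rotations up to an interpolation-
  # smoothing offset (the resampled texture reads slightly more severe)
  expect_lt(max(abs(r1$pairs$swes_original - r1$pairs$swes_rotated)), 2.5)
})

test_that("rotate_volume fills out-of-field voxels with air", {
  ph <- generate_phantom(small_spec(severity = 0, seed = 1))
  rot <- rotate_volume(ph$volume, c(7.5, 7.5, 7.5))
  expect_equal(dim(rot), dim(ph$volume))
  expect_lte(min(rot$voxels), -1000)
  ident <- rotate_volume(ph$volume, c(0, 0, 0))
  expect_equal(ident$voxels, ph$volume$voxels)
})
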