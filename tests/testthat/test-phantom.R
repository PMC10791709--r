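test_that("zero-severity noise-free phantom has no low-attenuation lung", {
  spec <- small_spec(severity = 0, seed = 3, parenchyma_hu_sd = 0,
                     noise_sd = 0)
  ph <- generate_phantom(spec)
  lung <- ph$mask$labels > 0
  expect_gt(sum(lung), 0)
  expect_true(all(ph$volume$voxels[lung] >= -950))
  expect_equal(compute_lav950(ph$volume, ph$mask), 0)
})

test_that("phantom generation is deterministic for a fixed seed", {
  spec <- small_spec(severity = 4, seed = 9)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$labels, b$mask$labels)
  expect_identical(a$truth$label, b$truth$label)
})

test_that("higher severity strictly increases lesion-voxel count (brute force)", {
  count_lesions <- function(sev) {
    spec <- small_spec(severity = sev, seed = 5, noise_sd = 0,
                       parenchyma_hu_sd = 0, lesion_hu_sd = 0)
    ph <- generate_phantom(spec)
    # brute force: count replaced voxels one by one
    n <- 0L
    d <- dim(ph$volume$voxels)
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
      if (ph$mask$labels[i, j, k] > 0 && ph$volume$voxels[i, j, k] < -950)
        n <- n + 1L
    n
  }
  expect_gt(count_lesions(10), count_lesions(2))
})

test_that("per-slice lesion counts are monotone in slice severity", {
  nz <- 12
  lo <- matrix(runif(nz * 2, 0, 5), nz, 2,
               dimnames = list(NULL, c("right", "left")))
  hi <- pmin(lo + matrix(runif(nz * 2, 0, 5), nz, 2), 10)
  lesions_per_slice <- function(profile) {
    spec <- small_spec(seed = 7, noise_sd = 0, parenchyma_hu_sd = 0,
                       lesion_hu_sd = 0)
    spec$severity_profile <- profile
    ph <- generate_phantom(spec)
    vapply(seq_len(nz), function(k)
      sum(ph$volume$voxels[, , k][ph$mask$labels[, , k] > 0] < -950), 0L)
  }
  with_seed_test(21, {
    expect_true(all(lesions_per_slice(hi) >= lesions_per_slice(lo)))
  })
})

test_that("lesions lie inside the mask and lung compartments are disjoint", {
  # noise-free phantom with a unique lesion attenuation so lesion voxels
  # are unambiguously identifiable (background air sits at -1000)
  ph <- generate_phantom(small_spec(severity = 8, seed = 13, noise_sd = 0,
                                    parenchyma_hu_sd = 0,
                                    lesion_hu_mean = -980, lesion_hu_sd = 0))
  lesion <- ph$volume$voxels == -980
  expect_gt(sum(lesion), 0)
  expect_true(all(ph$mask$labels[lesion] > 0))
  expect_true(all(ph$mask$labels %in% 0:2))
  expect_equal(nrow(ph$truth), dim(ph$volume)[3] * 2)
})

test_that("oversized lung compartments are rejected with a sizing error", {
  expect_error(generate_phantom(small_spec(lung_scale = 2)), "lung_scale")
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(grid_shape = c(4, 24, 12)), "at least 8")
  expect_error(phantom_spec(severity_profile = 12), "\\[0, 10\\]")
  expect_error(phantom_spec(lesion_hu_mean = -900), "-950")
  expect_error(phantom_spec(spacing_mm = c(1, 1, 0)), "positive")
})

test_that("cohort with zero severity yields all-zero regional grades", {
  co <- suppressWarnings(
    simulate_cohort(3, severity_law = function(n) rep(0, n),
                    coupling = 0, seed = 2, spec = small_spec(),
                    profile_amplitude = 0))
  expect_true(all(co$records$sum_visual == 0L))
  for (ph in co$phantoms)
    expect_true(all(ph$regional_truth$grade == 0L))
})

test_that("noise-free spirometry link gives exact correlation -1", {
  co <- simulate_cohort(20, coupling = 0, seed = 4, spec = small_spec())
  expect_equal(cor(co$records$mean_severity, co$records$fev1_fvc), -1)
})

test_that("sample severity-spirometry correlation matches the analytic value", {
  # analytic r for y = a - b*m + e: r = -b*sd(m)/sqrt(b^2 var(m) + coupling^2)
  co <- simulate_cohort(200, coupling = 0.04, seed = 8, spec = small_spec())
  m <- co$records$mean_severity
  r_expected <- -0.035 * sd(m) / sqrt(0.035^2 * stats::var(m) + 0.04^2)
  r_obs <- cor(m, co$records$fev1_fvc)
  expect_lt(abs(r_obs - r_expected), 0.05)
})

test_that("cohort errors and warnings follow the contract", {
  expect_error(simulate_cohort(1), "at least 2")
  expect_warning(
    simulate_cohort(3, severity_law = function(n) rep(2, n), seed = 1,
                    spec = small_spec()),
    "degenerate")
})

test_that("record-level simulator produces valid labelled records", {
  rec <- simulate_records(50, seed = 6)
  expect_true(all(rec$sum_visual >= 0 & rec$sum_visual <= 18))
  expect_true(all(rec$fev1_fvc > 0.2 & rec$fev1_fvc < 1))
  expect_true(all(rec$lav950 >= 0 & rec$lav950 <= 1))
  expect_identical(rec$obstructed, rec$fev1_fvc < 0.7)
  expect_identical(rec$significant_emphysema, rec$sum_visual > 2L)
})
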