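test_that("volumes round-trip voxel-identically through every format", {
  ph <- generate_phantom(small_spec(severity = 3, seed = 2))
  td <- withr::local_tempdir()
  for (name in c("v.nii.gz", "v.nii", "v.mha", "v.mhd", "dcm_series")) {
    path <- file.path(td, name)
    write_volume(ph$volume, path)
    back <- read_volume(path)
    expect_identical(back$voxels, ph$volume$voxels, label = name)
    expect_equal(back$spacing, ph$volume$spacing, label = name)
  }
})

test_that("spacing survives round trip and masks keep integer labels", {
  vox <- array(round(rnorm(8 * 8 * 4, -500, 100)), c(8, 8, 4))
  vol <- ct_volume(vox, spacing = c(0.7, 0.7, 0.6))
  td <- withr::local_tempdir()
  f <- file.path(td, "v.nii.gz")
  write_volume(vol, f)
  # NIfTI stores pixdim in single precision
  expect_equal(read_volume(f)$spacing, c(0.7, 0.7, 0.6), tolerance = 1e-6)
  m <- lung_mask(array(sample(0:2, 8 * 8 * 4, replace = TRUE), c(8, 8, 4)),
                 spacing = c(0.7, 0.7, 0.6))
  fm <- file.path(td, "m.mha")
  write_volume(m, fm)
  expect_identical(read_mask(fm)$labels, m$labels)
})

test_that("DICOM slices are ordered by geometric z, not file name", {
  ph <- generate_phantom(small_spec(severity = 2, seed = 4, nz = 8))
  td <- withr::local_tempdir()
  dcm <- file.path(td, "series")
  write_volume(ph$volume, dcm)
  files <- list.files(dcm, full.names = TRUE)
  # shuffle by renaming so file order disagrees with z order
  shuffled <- file.path(dcm, sprintf("x_%04d.dcm", rev(seq_along(files))))
  file.rename(files, shuffled)
  back <- read_volume(dcm)
  expect_identical(back$voxels, ph$volume$voxels)
})

test_that("DICOM rescale slope/intercept arithmetic recovers HU", {
  # stored value 74 with slope 1, intercept -1024 must decode to -950 HU
  vox <- array(-950, c(8, 8, 2))
  td <- withr::local_tempdir()
  dcm <- file.path(td, "s")
  swescore:::write_dicom_series(vox, c(1, 1, 1), dcm,
                                rescale_intercept = -1024, rescale_slope = 1)
  raw_file <- readBin(list.files(dcm, full.names = TRUE)[1], "raw", 1e5)
  tags <- swescore:::parse_dicom_elements(raw_file)
  stored <- readBin(tags[["7FE0,0010"]], "integer", 64, size = 2,
                    signed = TRUE, endian = "little")
  expect_true(all(stored == 74))
  expect_true(all(read_volume(dcm)$voxels == -950))
})

test_that("mixed DICOM series are rejected naming the offending UIDs", {
  td <- withr::local_tempdir()
  dcm <- file.path(td, "mix")
  swescore:::write_dicom_series(array(0, c(4, 4, 1)), c(1, 1, 1), dcm,
                                series_uid = "1.2.3.4")
  file.rename(file.path(dcm, "slice_0001.dcm"), file.path(dcm, "a.dcm"))
  swescore:::write_dicom_series(array(0, c(4, 4, 1)), c(1, 1, 1), dcm,
                                series_uid = "1.2.3.5")
  expect_error(read_volume(dcm), "1\\.2\\.3\\.4.*1\\.2\\.3\\.5")
})

test_that("HU values outside the plausible range are clamped and counted", {
  vox <- array(-850, c(8, 8, 2))
  vox[1, 1, 1] <- -2000
  vox[2, 1, 1] <- 5000
  vol <- ct_volume(vox, c(1, 1, 1))
  expect_equal(attr(vol, "n_clamped"), 2)
  expect_equal(vol$voxels[1, 1, 1], -1100)
  expect_equal(vol$voxels[2, 1, 1], 3100)
})

test_that("patient tables validate the sum-visual scale and allow missing DLco", {
  td <- withr::local_tempdir()
  f <- file.path(td, "pat.csv")
  writeLines(c(
    "patient_id,swes,lav950,sum_visual,fev1_fvc,dlco_pred_pct",
    "P1,1.2,0.05,18,0.78,93",
    "P2,0.4,0.02,0,0.81,"), f)
  tab <- read_patient_table(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$sum_visual, c(18L, 0L))
  expect_true(is.na(tab$dlco_pred_pct[2]))
  expect_false(tab$obstructed[1])

  writeLines(c(
    "patient_id,swes,lav950,sum_visual,fev1_fvc,dlco_pred_pct",
    "P1,1.2,0.05,19,0.78,93"), f)
  expect_error(read_patient_table(f), "sum_visual")
})

test_that("annotation tables round-trip through CSV", {
  tr <- blocks_to_slices(c(0, 2, 3), z_spacing_mm = 5, side = "left",
                         patient_id = "P1")
  ten <- refine_to_ten(median_z_filter(tr))
  td <- withr::local_tempdir()
  f <- file.path(td, "ann.csv")
  write_annotations(ten, f)
  back <- read_annotations(f)
  expect_equal(back$label, ten$label)
  expect_equal(track_scale(back), "ten_degree")
})
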