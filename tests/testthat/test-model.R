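test_that("contrast windowing maps the HU window affinely onto [0, 1]", {
  mk <- function(hu) {
    labels <- array(1L, c(10, 10, 1))
    vol <- ct_volume(array(hu, c(10, 10, 1)), c(1, 1, 1))
    preprocess_slice(vol, lung_mask(labels, c(1, 1, 1)), 0, "right",
                     input_size = 8)
  }
  expect_true(all(mk(-1100)$image == 0))
  expect_true(all(mk(100)$image == 1))
  expect_true(all(mk(-500)$image == 0.5))   # window center -500, width 1200
})

test_that("non-lung pixels are zero and left lungs are mirrored", {
  vox <- array(-850, c(12, 12, 1))
  labels <- array(0L, c(12, 12, 1))
  labels[2:5, 4:9, 1] <- 2L
  vol <- ct_volume(vox, c(1, 1, 1))
  m <- lung_mask(labels, c(1, 1, 1))
  s_left <- preprocess_slice(vol, m, 0, "left", input_size = 8)
  expect_true(all(s_left$image >= 0 & s_left$image <= 1))
  labels_r <- array(0L, c(12, 12, 1))
  labels_r[rev(13 - (2:5)), 4:9, 1] <- 1L
  s_right <- preprocess_slice(vol, lung_mask(labels_r, c(1, 1, 1)),
                              0, "right", input_size = 8)
  expect_equal(s_left$image, s_right$image)  # mirrored left == mirrored-placed right
  expect_error(preprocess_slice(vol, m, 0, "right", input_size = 8),
               "no lung")
})

test_that("oversampling grows rare bins to the target fraction", {
  samples <- toy_samples(100)
  for (i in 1:100)
    samples[[i]]$label <- if (i <= 90) 0 else 8
  over <- oversample(samples, target = 0.25, seed = 3)
  bins <- swescore:::sample_bins(over)
  expect_gte(sum(bins == 8L), 23)        # ceiling(0.25 * 90)
  expect_equal(sum(bins == 0L), 90)
  expect_identical(vapply(oversample(samples, seed = 9), `[[`, 0, "label"),
                   vapply(oversample(samples, seed = 9), `[[`, 0, "label"))
  balanced <- samples[1:20]
  for (i in 1:20) balanced[[i]]$label <- rep(c(0, 8), each = 10)[i]
  expect_identical(oversample(balanced, seed = 1), balanced)
  onebin <- samples[1:5]
  for (i in 1:5) onebin[[i]]$label <- 2
  expect_warning(oversample(onebin), "one label bin")
})

test_that("the weighted loss follows its closed form", {
  w1 <- c("0" = 1, "2" = 1)
  expect_equal(weighted_loss(c(0, 2), c(0, 2), w1), 0)
  expect_equal(weighted_loss(4, 2, c("2" = 1)), 6)   # 2^2 + |2|
  w <- loss_weights(c(0, 0, 0, 8))
  expect_equal(weighted_loss(c(1, 1, 1, 7), c(0, 0, 0, 8), 2 * w),
               2 * weighted_loss(c(1, 1, 1, 7), c(0, 0, 0, 8), w))
  expect_error(weighted_loss(1, 5, c("0" = 1)), "no loss weight")
})

test_that("loss weights are inverse bin proportions on the oversampled set", {
  w <- loss_weights(c(0, 0, 0, 5))
  expect_equal(unname(w["0"]), 4 / 3)
  expect_equal(unname(w["5"]), 4)
  expect_true(all(is.finite(w) & w > 0))
})

test_that("patient-level splits never leak a patient across sets", {
  with_seed_test(5, {
    for (i in 1:50) {
      patients <- sprintf("P%02d", seq_len(sample(3:20, 1)))
      val <- swescore:::patient_split(patients, runif(1, 0.1, 0.5),
                                      seed = sample.int(1e6, 1))
      expect_gt(length(val), 0)
      expect_lt(length(val), length(patients))
      expect_true(all(val %in% patients))
    }
  })
})

test_that("training reduces the loss, selects the best epoch, and is seeded", {
  samples <- toy_samples(120, seed = 2)
  cfg <- train_config(epochs = 3, n_seeds = 1, input_size = 24,
                      batch_size = 16, seed = 4)
  fit <- train_regressor(samples, cfg, quiet = TRUE)
  h <- fit$history
  expect_equal(nrow(h), 3)
  expect_lt(h$train_loss[3], h$train_loss[1])
  expect_equal(h$epoch[h$selected], h$epoch[which.min(h$val_loss)])
  fit2 <- train_regressor(samples, cfg, quiet = TRUE)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
})

test_that("training rejects degenerate inputs", {
  samples <- toy_samples(20, seed = 3)
  for (i in seq_along(samples)) samples[[i]]$patient_id <- "only_one"
  expect_error(train_regressor(samples, train_config(epochs = 1, n_seeds = 1,
                                                     input_size = 24)),
               "at least 2 patients")
})

test_that("binned accuracy counts predictions within the tolerance band", {
  expect_equal(binned_accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(binned_accuracy(c(3, 4), c(1, 2)), 0)
  expect_equal(binned_accuracy(c(1.4, 7.0, 9.0), c(0, 5, 10)), 2 / 3)
  expect_equal(binned_accuracy(c(1.5, 0), c(0, 5)), 0.5)  # boundary included
  expect_error(binned_accuracy(numeric(0), numeric(0)), "empty")
})

test_that("slice predictions cover exactly the lung-bearing pairs, clamped", {
  fix <- trained_fixture()
  ph <- fix$test_phantoms[[1]]
  preds <- predict_slices(fix$model, ph$volume, ph$mask)
  expect_true(all(preds$label >= 0 & preds$label <= 10))
  ar <- slice_areas(ph$mask)
  with_lung <- ar[ar$area_mm2 > 0, c("slice_index", "side")]
  got <- dplyr::arrange(preds[, c("slice_index", "side")],
                        side, slice_index)
  want <- dplyr::arrange(with_lung, side, slice_index)
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
  bad_mask <- lung_mask(ph$mask$labels[, , 1, drop = FALSE],
                        ph$mask$spacing)
  expect_error(predict_slices(fix$model, ph$volume, bad_mask),
               "different grid")
})

test_that("trained predictions track phantom severity order", {
  fix <- trained_fixture()
  sev9 <- fix$preds[fix$labs >= 8]
  sev1 <- fix$preds[fix$labs <= 2]
  expect_gt(mean(sev9), mean(sev1))
})
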