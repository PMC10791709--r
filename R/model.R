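#' Preprocess one CT slice-lung into a network input
#'
#' Prediction-time preprocessing uses only segmentation, contrast windowing,
#' cropping and resizing: non-lung pixels are set to the window floor, HU is
#' windowed at level −500 / width 1200 (clipped to \[−1100, 100\]) and mapped
#' affinely to \[0, 1\], the slice is cropped to the lung side's bounding box
#' padded by 5%, resized bilinearly to `input_size`, and left lungs are
#' mirrored horizontally so both sides share one orientation.
#'
#' @param volume A [ct_volume].
#' @param mask The paired [lung_mask].
#' @param slice_index 0-based slice index.
#' @param side `"right"` or `"left"`.
#' @param input_size Output image side length in pixels.
#' @param label Optional ten-degree training label to attach.
#' @return A `slice_sample`: list with `image` (`input_size` square matrix in
#'   \[0, 1\]), `side`, `slice_index`, `patient_id`, `label`.
#' @export
preprocess_slice <- function(volume, mask, slice_index, side,
                             input_size = 64, label = NA_real_) {
  check_paired_geometry(volume, mask)
  k <- slice_index + 1L
  if (k < 1 || k > dim(volume$voxels)[3]) abort("slice_index out of range.")
  side_label <- if (side == "right") 1L else 2L
  m <- mask$labels[, , k] == side_label
  if (!any(m)) abort(sprintf("no lung in slice %d (%s).", slice_index, side))
  hu <- volume$voxels[, , k]
  img <- (pmin(pmax(hu, -1100), 100) + 1100) / 1200
  img[!m] <- 0
  xr <- range(which(rowSums(m) > 0))
  yr <- range(which(colSums(m) > 0))
  pad_x <- max(1L, round(0.05 * (xr[2] - xr[1] + 1)))
  pad_y <- max(1L, round(0.05 * (yr[2] - yr[1] + 1)))
  xs <- max(1L, xr[1] - pad_x):min(nrow(img), xr[2] + pad_x)
  ys <- max(1L, yr[1] - pad_y):min(ncol(img), yr[2] + pad_y)
  crop <- img[xs, ys, drop = FALSE]
  out <- resize_bilinear_2d(crop, input_size, input_size)
  if (side == "left") out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  structure(
    list(image = out, side = side, slice_index = as.integer(slice_index),
         patient_id = volume$patient_id, label = label),
    class = "slice_sample")
}

#' Build a slice-wise emphysema regression network
#'
#' An 18-layer residual convolutional network ("full" variant: the standard
#' four-stage basic-block configuration with widths 64/128/256/512, adapted
#' to one input channel, whose final fully connected stage is a single
#' neuron emitting the slice emphysema score) or a reduced-depth variant
#' (three stages of one basic block, widths 8/16/32) for desk-scale
#' training. Weight initialization is seeded and reproducible.
#'
#' @param input_size Input image side length in pixels.
#' @param seed Seed for weight initialization.
#' @param variant `"reduced"` or `"full"`.
#' @return A `slice_regressor` object.
#' @export
build_model <- function(input_size = 256, seed = 1L,
                        variant = c("reduced", "full")) {
  variant <- match.arg(variant)
  arch <- nn_arch(variant, input_size)
  P <- with_seed(seed, nn_init_params(arch))
  structure(
    list(arch = arch, params = P, run_stats = nn_init_runstats(P),
         input_size = input_size, variant = variant, seed = as.integer(seed),
         trained = FALSE, history = NULL, config = NULL),
    class = "slice_regressor")
}

#' @export
print.slice_regressor <- function(x, ...) {
  cat(sprintf("<slice_regressor> %s variant, %d parameters, input %dx%d%s\n",
              x$variant, nn_param_count(x$params), x$input_size, x$input_size,
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

#' Predict scores for a batch of slice samples
#'
#' @param object A `slice_regressor`.
#' @param newdata List of `slice_sample` objects (or a single one).
#' @param ... Unused.
#' @return Numeric vector of raw (unclamped) slice scores.
#' @export
predict.slice_regressor <- function(object, newdata, ...) {
  if (inherits(newdata, "slice_sample")) newdata <- list(newdata)
  x <- samples_to_batch(newdata)
  nn_forward(object$params, object$arch, object$run_stats, x,
             training = FALSE)$pred
}

samples_to_batch <- function(samples) {
  h <- nrow(samples[[1]]$image)
  x <- array(0, c(h, h, 1, length(samples)))
  for (i in seq_along(samples)) x[, , 1, i] <- samples[[i]]$image
  x
}

#' Training configuration for the slice regressor
#'
#' Defaults are the reference regimen: 75 epochs, batch size 32, learning
#' rate 0.001 exponentially decayed with a power of 0.95 at each epoch, L2
#' penalty weight 1e-6, Adam with default parameters, five random seeds, and
#' oversampling of rare label bins to at least 25% of the largest bin.
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay_power_per_epoch Multiplicative LR decay per epoch.
#' @param l2_weight L2 regularization weight.
#' @param n_seeds Number of independent training replicates.
#' @param input_size Network input side length.
#' @param oversampling_target Minimum bin size as a fraction of the largest
#'   label bin after oversampling.
#' @param validation_fraction Fraction of patients held out for validation.
#' @param variant Network variant, `"reduced"` or `"full"`.
#' @param seed Base RNG seed (split/oversampling/replicate seeds derive from
#'   it).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 75, batch_size = 32, learning_rate = 0.001,
                         lr_decay_power_per_epoch = 0.95, l2_weight = 1e-6,
                         n_seeds = 5, input_size = 256,
                         oversampling_target = 0.25,
                         validation_fraction = 0.2,
                         variant = "reduced", seed = 1L) {
  if (epochs < 1) abort("`epochs` must be at least 1.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (lr_decay_power_per_epoch <= 0 || lr_decay_power_per_epoch > 1)
    abort("`lr_decay_power_per_epoch` must lie in (0, 1].")
  if (n_seeds < 1) abort("`n_seeds` must be at least 1.")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate,
         lr_decay_power_per_epoch = lr_decay_power_per_epoch,
         l2_weight = l2_weight, n_seeds = as.integer(n_seeds),
         input_size = as.integer(input_size),
         oversampling_target = oversampling_target,
         validation_fraction = validation_fraction,
         variant = variant, seed = as.integer(seed)),
    class = "train_config")
}

# Validation patients for a patient-level (never slice-level) split.
patient_split <- function(patients, fraction, seed) {
  n_val <- max(1L, round(fraction * length(patients)))
  if (n_val >= length(patients))
    abort("validation split would swallow all patients.")
  with_seed(seed, sample(patients, n_val))
}

sample_bins <- function(samples) {
  labels <- vapply(samples, `[[`, 0, "label")
  as.integer(round(pmin(pmax(labels, 0), 10)))
}

#' Oversample rare label bins
#'
#' Slice labels are binned to integers 0–10; every non-empty bin is grown by
#' resampling with replacement until it holds at least `target` times the
#' size of the largest bin, partially compensating the label imbalance.
#' Deterministic for a fixed seed.
#'
#' @param samples List of `slice_sample` objects with labels.
#' @param target Minimum bin size as a fraction of the largest bin.
#' @param seed RNG seed.
#' @return The oversampled list of samples.
#' @export
oversample <- function(samples, target = 0.25, seed = 1L) {
  bins <- sample_bins(samples)
  tab <- table(bins)
  if (length(tab) == 1) {
    warn("all samples fall in one label bin; nothing to oversample.")
    return(samples)
  }
  goal <- ceiling(target * max(tab))
  with_seed(seed, {
    extra <- integer(0)
    for (b in names(tab)) {
      n_b <- tab[[b]]
      if (n_b < goal) {
        idx <- which(bins == as.integer(b))
        extra <- c(extra, sample(idx, goal - n_b, replace = TRUE))
      }
    }
    c(samples, samples[extra])
  })
}

#' Inverse-proportion loss weights per label bin
#'
#' One weight per non-empty integer label bin, the inverse of the bin's
#' proportion in the (oversampled) training set, balancing rare labels.
#'
#' @param labels Numeric ten-degree labels.
#' @return Named numeric vector of weights keyed by bin "0".."10".
#' @export
loss_weights <- function(labels) {
  bins <- as.integer(round(pmin(pmax(labels, 0), 10)))
  tab <- table(bins)
  w <- length(bins) / as.numeric(tab)
  names(w) <- names(tab)
  w
}

#' Imbalance-weighted regression loss
#'
#' Mean over samples of `w_bin(label) * ((pred - label)^2 + |pred - label|)`:
#' the sum of squared and absolute error, weighted by the inverse label-bin
#' proportion.
#'
#' @param predictions,labels Equal-length numeric vectors.
#' @param weights Named weights from [loss_weights()]; every label's bin must
#'   be present.
#' @return The scalar loss.
#' @export
weighted_loss <- function(predictions, labels, weights) {
  if (length(predictions) != length(labels))
    abort("predictions and labels must have equal length.")
  w <- lookup_weights(labels, weights, strict = TRUE)
  mean(w * ((predictions - labels)^2 + abs(predictions - labels)))
}

lookup_weights <- function(labels, weights, strict = FALSE) {
  bins <- as.integer(round(pmin(pmax(labels, 0), 10)))
  hit <- match(as.character(bins), names(weights))
  if (anyNA(hit)) {
    if (strict)
      abort(sprintf("no loss weight for label bin(s): %s",
                    paste(unique(bins[is.na(hit)]), collapse = ", ")))
    # nearest available bin (validation data may hold bins unseen in training)
    avail <- as.integer(names(weights))
    hit[is.na(hit)] <- vapply(bins[is.na(hit)], function(b)
      which.min(abs(avail - b)), 0L)
  }
  as.numeric(weights)[hit]
}

weighted_loss_grad <- function(predictions, labels, w) {
  d <- predictions - labels
  w * (2 * d + sign(d)) / length(predictions)
}

#' Train the slice-wise emphysema regressor
#'
#' Splits patients (never slices) into training and validation sets,
#' oversamples rare label bins, and optimizes the imbalance-weighted
#' MSE+MAE loss with Adam (default parameters), per-epoch exponential
#' learning-rate decay and L2 regularization. The model is evaluated on the
#' validation split every epoch and the returned checkpoint is the one with
#' the lowest validation loss. With `n_seeds > 1` the whole procedure runs
#' once per seed and the best replicate (lowest validation loss) is
#' returned; all replicates' histories are kept.
#'
#' @param samples List of labelled `slice_sample` objects spanning >= 2
#'   label bins and >= 2 patients.
#' @param config A [train_config()].
#' @param quiet Suppress per-epoch progress messages.
#' @return A trained `slice_regressor`; `$history` holds a tibble with
#'   `seed`, `epoch`, `train_loss`, `val_loss`, `selected`.
#' @export
train_regressor <- function(samples, config = train_config(), quiet = FALSE) {
  patients <- unique(vapply(samples, `[[`, "", "patient_id"))
  if (length(patients) < 2)
    abort("need at least 2 patients for a patient-level split.")
  val_patients <- patient_split(patients, config$validation_fraction,
                                config$seed)
  is_val <- vapply(samples, function(s) s$patient_id %in% val_patients, TRUE)
  train_set <- samples[!is_val]
  val_set <- samples[is_val]
  if (length(val_set) == 0) abort("validation split is empty.")
  if (length(unique(sample_bins(train_set))) < 2)
    abort("training data must span at least 2 label bins.")
  train_set <- oversample(train_set, target = config$oversampling_target,
                          seed = config$seed + 1L)
  train_labels <- vapply(train_set, `[[`, 0, "label")
  weights <- loss_weights(train_labels)
  val_x <- samples_to_batch(val_set)
  val_y <- vapply(val_set, `[[`, 0, "label")
  val_w <- lookup_weights(val_y, weights)
  histories <- list()
  best <- NULL
  for (rep_i in seq_len(config$n_seeds)) {
    seed_i <- config$seed + 100L * rep_i
    model <- build_model(config$input_size, seed = seed_i,
                         variant = config$variant)
    fit <- with_seed(seed_i + 1L,
      fit_one_seed(model, train_set, train_labels, weights,
                   val_x, val_y, val_w, config, quiet))
    histories[[rep_i]] <- dplyr::mutate(fit$history, seed = seed_i,
                                        .before = 1)
    if (is.null(best) || fit$best_val < best$best_val) best <- fit
  }
  model <- best$model
  model$trained <- TRUE
  model$config <- config
  model$history <- dplyr::bind_rows(histories)
  model
}

fit_one_seed <- function(model, train_set, train_labels, weights,
                         val_x, val_y, val_w, config, quiet) {
  P <- model$params
  rs <- model$run_stats
  opt <- adam_init(P)
  n <- length(train_set)
  w_all <- lookup_weights(train_labels, weights)
  hist <- vector("list", config$epochs)
  best_val <- Inf; best_P <- P; best_rs <- rs; best_epoch <- NA_integer_
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      config$lr_decay_power_per_epoch^(epoch - 1)
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      x <- samples_to_batch(train_set[bi])
      y <- train_labels[bi]
      w <- w_all[bi]
      fw <- nn_forward(P, model$arch, rs, x, training = TRUE)
      rs <- fw$rs
      d <- fw$pred - y
      ep_loss <- ep_loss + sum(w * (d^2 + abs(d)))
      dpred <- weighted_loss_grad(fw$pred, y, w)
      G <- nn_backward(P, model$arch, fw$caches, dpred)
      upd <- adam_step(P, G, opt, lr, l2 = config$l2_weight)
      P <- upd$P; opt <- upd$state
    }
    train_loss <- ep_loss / n
    val_pred <- nn_forward(P, model$arch, rs, val_x, training = FALSE)$pred
    dv <- val_pred - val_y
    val_loss <- mean(val_w * (dv^2 + abs(dv)))
    hist[[epoch]] <- tibble(epoch = epoch, train_loss = train_loss,
                            val_loss = val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss; best_P <- P; best_rs <- rs; best_epoch <- epoch
    }
    if (!quiet)
      inform(sprintf("epoch %d/%d: train %.4f, val %.4f", epoch,
                     config$epochs, train_loss, val_loss))
  }
  history <- dplyr::bind_rows(hist)
  history$selected <- history$epoch == best_epoch
  model$params <- best_P
  model$run_stats <- best_rs
  list(model = model, history = history, best_val = best_val,
       best_epoch = best_epoch)
}

#' Predict per-slice, per-lung emphysema scores for a volume
#'
#' Runs the trained regressor over every (slice, side) pair that contains
#' lung voxels; slices without lung are omitted. Scores are clamped to the
#' annotation scale \[0, 10\].
#'
#' @param model A trained `slice_regressor`.
#' @param volume A [ct_volume].
#' @param mask The paired [lung_mask].
#' @param batch_size Slices per forward batch.
#' @return A ten-degree `slice_track` of predictions.
#' @export
predict_slices <- function(model, volume, mask, batch_size = 64) {
  stopifnot(inherits(model, "slice_regressor"))
  check_paired_geometry(volume, mask)
  d <- dim(volume$voxels)
  pairs <- list()
  for (side in c("right", "left")) {
    side_label <- if (side == "right") 1L else 2L
    present <- which(apply(mask$labels == side_label, 3, any))
    for (k in present)
      pairs[[length(pairs) + 1L]] <- list(slice_index = k - 1L, side = side)
  }
  if (length(pairs) == 0) abort("mask contains no lung voxels.")
  samples <- lapply(pairs, function(p)
    preprocess_slice(volume, mask, p$slice_index, p$side,
                     input_size = model$input_size))
  preds <- numeric(length(samples))
  for (start in seq(1, length(samples), by = batch_size)) {
    sel <- start:min(start + batch_size - 1, length(samples))
    preds[sel] <- predict(model, samples[sel])
  }
  new_slice_track(
    tibble(patient_id = volume$patient_id,
           slice_index = vapply(pairs, `[[`, 0L, "slice_index"),
           side = vapply(pairs, `[[`, "", "side"),
           label = pmin(pmax(preds, 0), 10)),
    scale = "ten_degree")
}

#' Fraction of predictions within a tolerance of their labels
#'
#' The slice-level outcome measure: the fraction of predictions within
#' ±`tolerance` of the slice emphysema annotation.
#'
#' @param predictions,labels Equal-length nonempty numeric vectors.
#' @param tolerance Half-width of the accuracy band.
#' @return Fraction in \[0, 1\].
#' @export
binned_accuracy <- function(predictions, labels, tolerance = 1.5) {
  if (length(predictions) == 0) abort("empty input.")
  if (length(predictions) != length(labels))
    abort("predictions and labels must have equal length.")
  mean(abs(predictions - labels) <= tolerance)
}

#' @export
glance.slice_regressor <- function(x, ...) {
  h <- x$history
  sel <- if (!is.null(h)) h[h$selected, ] else NULL
  tibble(
    variant = x$variant,
    n_parameters = nn_param_count(x$params),
    input_size = x$input_size,
    trained = x$trained,
    selected_epoch = if (!is.null(sel) && nrow(sel)) sel$epoch[which.min(sel$val_loss)] else NA_integer_,
    best_val_loss = if (!is.null(sel) && nrow(sel)) min(sel$val_loss) else NA_real_)
}
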