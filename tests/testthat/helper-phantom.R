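# Shared fixtures, built in code. The trained-model fixture is expensive
# (phantom cohort + CNN training), so it is built lazily once per run and
# cached for every test that needs it.

small_spec <- function(severity = 0, seed = 1, nz = 12, ...) {
  phantom_spec(grid_shape = c(24, 24, nz), spacing_mm = c(6, 6, 6),
               severity_profile = severity, seed = seed, ...)
}

desk_spec <- function(...) {
  phantom_spec(grid_shape = c(40, 40, 18), spacing_mm = c(6, 6, 6), ...)
}

phantom_slice_samples <- function(phantoms, input_size = 48) {
  out <- list()
  for (ph in phantoms) {
    tr <- ph$truth
    for (i in seq_len(nrow(tr))) {
      s <- tryCatch(
        preprocess_slice(ph$volume, ph$mask, tr$slice_index[i], tr$side[i],
                         input_size = input_size, label = tr$label[i]),
        error = function(e) NULL)
      if (!is.null(s)) out[[length(out) + 1L]] <- s
    }
  }
  out
}

# Flat synthetic slice samples with a direct image-level severity signal,
# for optimizer tests that do not need phantom realism.
toy_samples <- function(n, seed = 1, size = 24) {
  with_seed_test(seed, lapply(seq_len(n), function(i) {
    label <- runif(1, 0, 10)
    img <- matrix(pmin(pmax(label / 10 + rnorm(size * size, 0, 0.05), 0), 1),
                  size, size)
    structure(list(image = img, side = "right", slice_index = 0L,
                   patient_id = sprintf("T%02d", (i %% 8) + 1L),
                   label = label),
              class = "slice_sample")
  }))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

.fixture_env <- new.env(parent = emptyenv())

# Cohort of 36 desk-scale phantoms (26 train / 10 held out), a reduced-depth
# regressor trained for 10 epochs, held-out slice predictions, and per-
# phantom SWES / LAV950 on the held-out set.
trained_fixture <- function() {
  if (!is.null(.fixture_env$fix)) return(.fixture_env$fix)
  co <- simulate_cohort(36, seed = 11, spec = desk_spec())
  train_ph <- co$phantoms[1:26]
  test_ph <- co$phantoms[27:36]
  samples <- phantom_slice_samples(train_ph)
  cfg <- train_config(epochs = 10, n_seeds = 1, input_size = 48, seed = 5)
  model <- train_regressor(samples, cfg, quiet = TRUE)
  test_samples <- phantom_slice_samples(test_ph)
  preds <- pmin(pmax(predict(model, test_samples), 0), 10)
  labs <- vapply(test_samples, `[[`, 0, "label")
  scored <- dplyr::bind_rows(lapply(test_ph, function(ph) {
    m <- segment_lungs(ph$volume)
    tibble::tibble(
      patient_id = ph$patient_id,
      swes = compute_swes(predict_slices(model, ph$volume, m),
                          slice_areas(m)),
      lav950 = compute_lav950(ph$volume, m),
      mean_severity = ph$mean_severity)
  }))
  records <- dplyr::inner_join(
    scored,
    co$records[, c("patient_id", "sum_visual", "fev1_fvc", "dlco_pred_pct")],
    by = "patient_id")
  .fixture_env$fix <- list(
    cohort = co, model = model, n_train_slices = length(samples),
    test_phantoms = test_ph, test_samples = test_samples,
    preds = preds, labs = labs, records = label_patients(records))
  .fixture_env$fix
}

random_four_degree_track <- function(n_blocks, z_spacing_mm = 5,
                                     side = "right") {
  blocks_to_slices(sample(0:3, n_blocks, replace = TRUE),
                   z_spacing_mm = z_spacing_mm, side = side)
}
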