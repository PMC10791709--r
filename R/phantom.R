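#' Specification of a synthetic chest-CT phantom
#'
#' The phantom emulates a thin-slice unenhanced chest CT: a soft-tissue body
#' ellipse surrounded by air, containing two disjoint ellipsoidal lung
#' compartments of healthy parenchyma (about −850 HU). Emphysema is emulated
#' by replacing, slice by slice, a severity-dependent fraction of parenchyma
#' voxels with low-attenuation lesion voxels (below −950 HU), placed as
#' spatially clustered blobs rather than independent voxels so that lesions
#' have the regional character of real emphysema and a learnable texture.
#'
#' The severity → lesion-fraction map is `f(s) = 0.06 * s`, i.e. 0% of the
#' lung cross-section at severity 0 up to 60% at severity 10, spanning the
#' low-attenuation fractions seen in population cohorts at low-to-mid
#' severities.
#'
#' @param grid_shape Voxels per axis (x, y, z); all at least 8.
#' @param spacing_mm Voxel size in mm per axis; all positive.
#' @param body_hu Soft-tissue background attenuation, HU.
#' @param parenchyma_hu_mean,parenchyma_hu_sd Healthy lung attenuation, HU.
#' @param lesion_hu_mean,lesion_hu_sd Emphysematous attenuation, HU; the mean
#'   must lie below −950 while the parenchyma mean lies above it.
#' @param severity_profile Per-slice, per-lung true severity on \[0, 10\]: a
#'   single number, a length-`nz` vector (shared by both lungs), or an
#'   `nz x 2` matrix with columns `right`, `left`.
#' @param noise_sd Additive acquisition noise, HU.
#' @param lung_scale Relative size of the lung compartments; values much
#'   above 1 make the compartments overlap or leave the body outline and are
#'   rejected.
#' @param seed RNG seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [simulate_cohort()]
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         spacing_mm = c(5, 5, 5),
                         body_hu = 40,
                         parenchyma_hu_mean = -850, parenchyma_hu_sd = 40,
                         lesion_hu_mean = -1000, lesion_hu_sd = 25,
                         severity_profile = 0,
                         noise_sd = 20,
                         lung_scale = 1,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    abort("`grid_shape` must be three extents, each at least 8 voxels.")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    abort("`spacing_mm` must be three positive voxel sizes.")
  if (!(lesion_hu_mean < -950 && -950 < parenchyma_hu_mean))
    abort("need lesion_hu_mean < -950 < parenchyma_hu_mean.")
  profile <- normalize_severity_profile(severity_profile, grid_shape[3])
  if (any(profile < 0 | profile > 10))
    abort("severity_profile values must lie in [0, 10].")
  if (noise_sd < 0 || parenchyma_hu_sd < 0 || lesion_hu_sd < 0)
    abort("standard deviations must be non-negative.")
  structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm, body_hu = body_hu,
         parenchyma_hu_mean = parenchyma_hu_mean,
         parenchyma_hu_sd = parenchyma_hu_sd,
         lesion_hu_mean = lesion_hu_mean, lesion_hu_sd = lesion_hu_sd,
         severity_profile = profile, noise_sd = noise_sd,
         lung_scale = lung_scale, seed = as.integer(seed)),
    class = "phantom_spec")
}

normalize_severity_profile <- function(profile, nz) {
  if (is.matrix(profile)) {
    if (nrow(profile) != nz || ncol(profile) != 2)
      abort("matrix severity_profile must be nz x 2 (right, left).")
    colnames(profile) <- c("right", "left")
    return(profile)
  }
  if (length(profile) == 1) profile <- rep(profile, nz)
  if (length(profile) != nz)
    abort("severity_profile length must match the z extent.")
  cbind(right = as.numeric(profile), left = as.numeric(profile))
}

#' Severity to lesion-fraction map
#'
#' Fraction of lung cross-section replaced by low-attenuation lesion at a
#' given severity: `0.06 * severity`, zero at severity 0.
#'
#' @param severity Severity value(s) on \[0, 10\].
#' @return Lesion fraction(s) on \[0, 0.6\].
#' @export
lesion_fraction <- function(severity) 0.06 * severity

# Run code with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  body_ax <- 0.46 * d[1]; body_ay <- 0.40 * d[2]
  lx <- 0.17 * d[1] * spec$lung_scale
  ly <- 0.26 * d[2] * spec$lung_scale
  # keep a z margin so modest rigid rotations cannot sweep the lung apices
  # into the out-of-field region of a resampled copy
  lz <- 0.38 * d[3] * spec$lung_scale
  offset <- 0.22 * d[1]
  if (offset - lx <= 0)
    abort("lung compartments would overlap at this lung_scale; reduce it.")
  if (offset + lx >= body_ax || ly >= body_ay || lz >= 0.5 * d[3])
    abort("lung compartments exceed the body outline or grid; reduce lung_scale.")
  ii <- seq_len(d[1]); jj <- seq_len(d[2]); kk <- seq_len(d[3])
  body2d <- outer(((ii - cx) / body_ax)^2, ((jj - cy) / body_ay)^2, `+`) <= 1
  lung2d <- function(center_x) {
    # per-slice in-plane mask scale for an ellipsoid: radius shrinks with |z|
    lapply(kk, function(k) {
      rz <- 1 - ((k - cz) / lz)^2
      if (rz <= 0) return(matrix(FALSE, d[1], d[2]))
      outer(((ii - center_x) / (lx * sqrt(rz)))^2,
            ((jj - cy) / (ly * sqrt(rz)))^2, `+`) <= 1
    })
  }
  list(body2d = body2d,
       right = lung2d(cx - offset),   # right lung on the low-x side
       left = lung2d(cx + offset))
}

#' Generate a synthetic chest-CT phantom
#'
#' Builds the voxel volume, the ground-truth left/right lung mask, the
#' per-slice true severity track, regional visual-style grades (six lung
#' regions graded 0–3), and simulated spirometry. Deterministic for a fixed
#' spec and seed. Within each lung slice, exactly
#' `round(lesion_fraction(severity) * n_lung_voxels)` voxels are replaced by
#' lesion-attenuation voxels, grown as clustered blobs around randomly seeded
#' centers. All HU values are rounded to integers, as CT scanners store them.
#'
#' @param spec A [phantom_spec].
#' @param coupling SD of the Gaussian noise added to the simulated
#'   FEV1/FVC; 0 gives the deterministic affine link
#'   `fev1_fvc = 0.80 - 0.035 * mean_severity`.
#' @param dlco_noise_sd SD of the noise on simulated DLcoPred%
#'   (`98 - 3.5 * mean_severity` before noise).
#' @param patient_id Identifier attached to the outputs.
#' @return An object of class `phantom`: a list with `volume` ([ct_volume]),
#'   `mask` ([lung_mask]), `truth` (ten-degree slice track covering every
#'   slice and both sides), `regional_truth` (six region grades 0–3),
#'   `fev1_fvc`, `dlco_pred_pct`, `mean_severity` and the `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 12),
#'                                     severity_profile = 5, seed = 7))
#' ph$volume
#' @export
generate_phantom <- function(spec, coupling = 0, dlco_noise_sd = 0,
                             patient_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  geom <- phantom_geometry(spec)
  with_seed(spec$seed, {
    vox <- array(-1000, dim = d)
    labels <- array(0L, dim = d)
    body <- geom$body2d
    for (k in seq_len(d[3])) {
      slab <- vox[, , k]
      slab[body] <- spec$body_hu
      lab <- labels[, , k]
      for (side in c("right", "left")) {
        in_lung <- geom[[side]][[k]]
        n_vox <- sum(in_lung)
        if (n_vox == 0) next
        lab[in_lung] <- if (side == "right") 1L else 2L
        sev <- spec$severity_profile[k, side]
        n_lesion <- round(lesion_fraction(sev) * n_vox)
        lung_idx <- which(in_lung, arr.ind = TRUE)
        hu <- rnorm(n_vox, spec$parenchyma_hu_mean, spec$parenchyma_hu_sd)
        if (n_lesion > 0) {
          lesion_sel <- pick_clustered(lung_idx, n_lesion)
          hu[lesion_sel] <- rnorm(n_lesion, spec$lesion_hu_mean,
                                  spec$lesion_hu_sd)
        }
        slab[in_lung] <- hu
      }
      if (spec$noise_sd > 0)
        slab <- slab + rnorm(length(slab), 0, spec$noise_sd)
      vox[, , k] <- round(slab)
      labels[, , k] <- lab
    }
    truth <- new_slice_track(
      tibble(patient_id = patient_id,
             slice_index = rep(seq_len(d[3]) - 1L, 2L),
             side = rep(c("right", "left"), each = d[3]),
             label = c(spec$severity_profile[, "right"],
                       spec$severity_profile[, "left"])),
      scale = "ten_degree")
    lung_slices <- which(vapply(seq_len(d[3]), function(k)
      sum(geom$right[[k]]) + sum(geom$left[[k]]) > 0, TRUE))
    mean_severity <- mean(spec$severity_profile[lung_slices, ])
    regional <- regional_grades(spec$severity_profile, lung_slices)
    fev <- simulate_fev1_fvc(mean_severity, coupling)
    dlco <- simulate_dlco(mean_severity, dlco_noise_sd)
    structure(
      list(volume = ct_volume(vox, spec$spacing_mm, patient_id),
           mask = lung_mask(labels, spec$spacing_mm, patient_id),
           truth = truth, regional_truth = regional,
           fev1_fvc = fev, dlco_pred_pct = dlco,
           mean_severity = mean_severity,
           patient_id = patient_id, spec = spec),
      class = "phantom")
  })
}

# Choose n clustered voxels: grow blobs around sampled centers by taking the
# voxels nearest (plus jitter) to any center.
pick_clustered <- function(lung_idx, n_lesion) {
  n_vox <- nrow(lung_idx)
  if (n_lesion >= n_vox) return(seq_len(n_vox))
  n_centers <- max(1L, ceiling(n_lesion / 40))
  centers <- lung_idx[sample.int(n_vox, n_centers), , drop = FALSE]
  d2 <- rep(Inf, n_vox)
  for (c in seq_len(n_centers)) {
    dc <- (lung_idx[, 1] - centers[c, 1])^2 + (lung_idx[, 2] - centers[c, 2])^2
    d2 <- pmin(d2, dc)
  }
  order(d2 + runif(n_vox, 0, 2))[seq_len(n_lesion)]
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> '%s': mean severity %.2f, sum-visual %d, FEV1/FVC %.2f\n",
    x$patient_id, x$mean_severity, sum(x$regional_truth$grade), x$fev1_fvc))
  invisible(x)
}

# Six-region visual-style grades: mean severity over the upper/middle/lower
# third of each lung's z extent, binned at [0,1), [1,4), [4,7), [7,10].
regional_grades <- function(profile, lung_slices) {
  thirds <- split(lung_slices,
                  cut(seq_along(lung_slices), 3, labels = c("lower", "middle", "upper")))
  purrr::map_dfr(c("right", "left"), function(side)
    purrr::map_dfr(names(thirds), function(region) {
      m <- mean(profile[thirds[[region]], side])
      tibble(side = side, region = region, mean_severity = m,
             grade = grade_from_severity(m))
    }))
}

grade_from_severity <- function(m) {
  as.integer(cut(m, breaks = c(-Inf, 1, 4, 7, Inf), right = FALSE)) - 1L
}

simulate_fev1_fvc <- function(mean_severity, coupling) {
  raw <- 0.80 - 0.035 * mean_severity +
    if (coupling > 0) rnorm(length(mean_severity), 0, coupling) else 0
  pmin(pmax(raw, 0.2001), 0.9999)
}

simulate_dlco <- function(mean_severity, noise_sd) {
  raw <- 98 - 3.5 * mean_severity +
    if (noise_sd > 0) rnorm(length(mean_severity), 0, noise_sd) else 0
  pmin(pmax(raw, 20), 140)
}

#' Simulate a phantom validation cohort
#'
#' Draws a per-patient mean severity from `severity_law`, builds a smooth
#' per-slice, per-lung severity profile around it, generates the phantom CT
#' volume and ground truth for each patient, and simulates spirometry as a
#' decreasing affine function of mean severity plus Gaussian noise (SD =
#' `coupling`), clamped to (0.2, 1.0). Regional grades are derived by
#' averaging true severity over the upper/middle/lower thirds of each lung
#' and binning at fixed cut points; their sum over the six regions is the
#' 0–18 sum-visual analogue.
#'
#' @param n Number of patients (at least 2).
#' @param severity_law Function of `n` returning per-patient mean severities
#'   on \[0, 10\]; the default draws uniformly on \[0, 8\].
#' @param coupling SD of the spirometry noise; 0 makes the severity to
#'   FEV1/FVC link exactly affine (and their correlation −1).
#' @param seed RNG seed.
#' @param spec Template [phantom_spec] supplying geometry and attenuation;
#'   its severity profile and seed are replaced per patient.
#' @param profile_amplitude Amplitude of the smooth slice-to-slice severity
#'   variation around the patient mean.
#' @param dlco_noise_sd SD of the simulated DLcoPred% noise.
#' @return A `phantom_cohort`: list with `phantoms` (list of [generate_phantom()]
#'   outputs) and `records` (tibble of per-patient ground truth:
#'   `patient_id`, `mean_severity`, `sum_visual`, `fev1_fvc`,
#'   `dlco_pred_pct`).
#' @export
simulate_cohort <- function(n, severity_law = function(n) runif(n, 0, 8),
                            coupling = 0.04, seed = 1L,
                            spec = phantom_spec(),
                            profile_amplitude = 1.5,
                            dlco_noise_sd = 8) {
  if (n < 2) abort("a cohort needs at least 2 patients.")
  with_seed(seed, {
    means <- severity_law(n)
    if (length(means) != n || any(means < 0 | means > 10))
      abort("severity_law must return n values in [0, 10].")
    if (stats::var(means) == 0)
      warn("degenerate severity law: all patients share the same mean severity.")
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    nz <- spec$grid_shape[3]
    phantoms <- vector("list", n)
    for (i in seq_len(n)) {
      profile <- vapply(c(0, pi / 2), function(phase_shift) {
        phi1 <- runif(1, 0, 2 * pi); phi2 <- runif(1, 0, 2 * pi)
        z <- seq_len(nz) / nz
        pmin(pmax(means[i] +
                    profile_amplitude * sin(2 * pi * z + phi1 + phase_shift) +
                    0.5 * profile_amplitude * sin(4 * pi * z + phi2),
                  0), 10)
      }, numeric(nz))
      colnames(profile) <- c("right", "left")
      spec_i <- spec
      spec_i$severity_profile <- profile
      spec_i$seed <- seeds[i]
      phantoms[[i]] <- generate_phantom(
        spec_i, coupling = coupling, dlco_noise_sd = dlco_noise_sd,
        patient_id = sprintf("P%03d", i))
    }
    records <- purrr::map_dfr(phantoms, function(ph)
      tibble(patient_id = ph$patient_id,
             mean_severity = ph$mean_severity,
             sum_visual = sum(ph$regional_truth$grade),
             fev1_fvc = ph$fev1_fvc,
             dlco_pred_pct = ph$dlco_pred_pct))
    structure(list(phantoms = phantoms, records = records),
              class = "phantom_cohort")
  })
}

#' Simulate per-patient score records without images
#'
#' A record-level twin of [simulate_cohort()] for cohort-scale statistical
#' experiments: the SWES column carries the true mean severity (plus optional
#' measurement noise), the LAV950 column carries the severity-derived
#' low-attenuation fraction with additional independent noise (the regime in
#' which a texture-based score should out-correlate threshold densitometry),
#' and FEV1/FVC follows the affine-plus-noise spirometry link.
#'
#' @param n Number of patients.
#' @param coupling SD of the spirometry noise.
#' @param swes_noise_sd Measurement noise on the SWES column (severity scale).
#' @param lav_noise_sd Extra noise on the LAV950 column, expressed on the
#'   severity scale before conversion to a fraction.
#' @param seed RNG seed.
#' @return A patient-record tibble with `swes`, `lav950`, `sum_visual`,
#'   `fev1_fvc`, `dlco_pred_pct` and the flags from [label_patients()].
#' @export
simulate_records <- function(n, coupling = 0.04, swes_noise_sd = 0.3,
                             lav_noise_sd = 2, seed = 1L) {
  if (n < 2) abort("need at least 2 patients.")
  with_seed(seed, {
    m <- runif(n, 0, 8)
    swes <- pmax(m + rnorm(n, 0, swes_noise_sd), 0)
    lav950 <- pmin(pmax(lesion_fraction(m + rnorm(n, 0, lav_noise_sd)), 0), 1)
    sum_visual <- vapply(m, function(mi) {
      sum(grade_from_severity(pmin(pmax(mi + rnorm(6, 0, 1.2), 0), 10)))
    }, integer(1))
    records <- tibble(
      patient_id = sprintf("R%04d", seq_len(n)),
      swes = swes, lav950 = lav950,
      sum_visual = as.integer(sum_visual),
      fev1_fvc = simulate_fev1_fvc(m, coupling),
      dlco_pred_pct = simulate_dlco(m, 8),
      mean_severity = m)
    label_patients(records)
  })
}
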