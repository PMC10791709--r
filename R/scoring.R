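#' Slice-wise whole-lung emphysema score (SWES)
#'
#' Aggregates per-slice, per-lung emphysema scores into one patient score:
#' the average score over all slice-lung units, weighted by the segmented
#' lung area of each unit. By default both lungs are pooled into a single
#' weighted mean (`per_lung = FALSE`); the alternative averages the two
#' per-lung weighted means.
#'
#' @param predictions A ten-degree `slice_track` of per-slice scores.
#' @param areas A [slice_areas()] tibble; every prediction must have a
#'   matching positive area.
#' @param per_lung Average per-lung means instead of pooling.
#' @return The scalar SWES (arbitrary units on the 0–10 annotation scale).
#' @examples
#' tr <- new_slice_track(
#'   tibble::tibble(side = "right", slice_index = 0:1, label = c(1, 9)),
#'   scale = "ten_degree")
#' ar <- tibble::tibble(side = "right", slice_index = 0:1,
#'                      area_mm2 = c(10, 30))
#' compute_swes(tr, ar)  # (1*10 + 9*30) / 40 = 7
#' @export
compute_swes <- function(predictions, areas, per_lung = FALSE) {
  joined <- dplyr::inner_join(
    as_tibble(predictions)[, c("slice_index", "side", "label")],
    as_tibble(areas)[, c("slice_index", "side", "area_mm2")],
    by = c("slice_index", "side"))
  if (nrow(joined) < nrow(predictions))
    abort("every prediction needs a matching slice area.")
  joined <- joined[joined$area_mm2 > 0, ]
  if (nrow(joined) == 0 || sum(joined$area_mm2) <= 0)
    abort("total lung area is zero.")
  if (!per_lung)
    return(sum(joined$label * joined$area_mm2) / sum(joined$area_mm2))
  per <- dplyr::summarise(
    dplyr::group_by(joined, .data$side),
    swes = sum(.data$label * .data$area_mm2) / sum(.data$area_mm2))
  mean(per$swes)
}

#' Low-attenuation volume below a threshold (LAV950)
#'
#' Threshold densitometry: the fraction of lung voxels with attenuation
#' strictly below the threshold (default −950 HU). Reported as a fraction in
#' \[0, 1\]; multiply by 100 for the conventional percentage.
#'
#' @param volume A [ct_volume].
#' @param mask The paired [lung_mask]; must contain lung voxels.
#' @param threshold_hu Threshold in HU.
#' @return Fraction of lung voxels below the threshold.
#' @export
compute_lav950 <- function(volume, mask, threshold_hu = -950) {
  check_paired_geometry(volume, mask)
  lung <- mask$labels > 0L
  n_lung <- sum(lung)
  if (n_lung == 0) abort("mask contains no lung voxels.")
  sum(volume$voxels[lung] < threshold_hu) / n_lung
}

#' Score one patient volume
#'
#' Convenience wrapper: segments the lungs (unless a mask is supplied),
#' predicts slice scores, and returns the SWES and LAV950 as one record row.
#'
#' @param volume A [ct_volume].
#' @param model A trained `slice_regressor`.
#' @param mask Optional precomputed [lung_mask].
#' @return A one-row tibble with `patient_id`, `swes`, `lav950`.
#' @export
score_patient <- function(volume, model, mask = NULL) {
  if (is.null(mask)) mask <- segment_lungs(volume)
  preds <- predict_slices(model, volume, mask)
  tibble(patient_id = volume$patient_id,
         swes = compute_swes(preds, slice_areas(mask)),
         lav950 = compute_lav950(volume, mask))
}

#' Intra-scan rotation repeatability of SWES
#'
#' Repeats the whole scoring chain on randomly rotated copies of a volume:
#' for each rotation, three independent angles are drawn uniformly on
#' ±`max_angle_deg` for the x–y, x–z and y–z planes, the volume is rotated
#' about its center (trilinear interpolation, out-of-field filled with
#' −1024 HU so no spurious lung appears), lungs are re-segmented, slice
#' scores re-predicted and the SWES recomputed. Returns the paired scores
#' and their Bland–Altman agreement summary. Deterministic for a fixed seed;
#' rotations whose segmentation fails are skipped and counted.
#'
#' @param volume A [ct_volume].
#' @param model A trained `slice_regressor`.
#' @param max_angle_deg Maximum rotation per plane, degrees.
#' @param n_rotations Number of rotated copies (>= 1).
#' @param seed RNG seed for the angles.
#' @return A `swes_repeatability` object: list with `pairs` (tibble of
#'   `rotation`, angles, `swes_original`, `swes_rotated`), `bland_altman`
#'   (see [bland_altman()]; differences are original − rotated) and
#'   `n_skipped`.
#' @export
rotation_repeatability <- function(volume, model, max_angle_deg = 7.5,
                                   n_rotations = 10, seed = 1L) {
  if (n_rotations < 1) abort("`n_rotations` must be at least 1.")
  base_mask <- segment_lungs(volume)
  swes0 <- compute_swes(predict_slices(model, volume, base_mask),
                        slice_areas(base_mask))
  with_seed(seed, {
    rows <- vector("list", n_rotations)
    n_skipped <- 0L
    for (r in seq_len(n_rotations)) {
      ang <- runif(3, -max_angle_deg, max_angle_deg)
      rot <- rotate_volume(volume, ang)
      swes_r <- tryCatch({
        m <- segment_lungs(rot)
        compute_swes(predict_slices(model, rot, m), slice_areas(m))
      }, error = function(e) {
        inform(sprintf("rotation %d skipped: %s", r, conditionMessage(e)))
        NA_real_
      })
      if (is.na(swes_r)) { n_skipped <- n_skipped + 1L; next }
      rows[[r]] <- tibble(rotation = r, angle_xy = ang[1], angle_xz = ang[2],
                          angle_yz = ang[3], swes_original = swes0,
                          swes_rotated = swes_r)
    }
    pairs <- dplyr::bind_rows(rows)
    if (nrow(pairs) == 0) abort("all rotations failed segmentation.")
    ba <- if (nrow(pairs) >= 2)
      bland_altman(pairs$swes_original, pairs$swes_rotated) else NULL
    structure(list(pairs = pairs, bland_altman = ba, n_skipped = n_skipped),
              class = "swes_repeatability")
  })
}

#' Rotate a CT volume about its center
#'
#' Composes the three in-plane rotations (x–y, x–z, y–z) in physical
#' coordinates and resamples with trilinear interpolation; voxels mapped
#' from outside the original field take the fill value (−1024 HU, air).
#'
#' @param volume A [ct_volume].
#' @param angles_deg Length-3 vector of rotation angles in degrees for the
#'   x–y, x–z and y–z planes.
#' @param fill_hu Fill value for out-of-field voxels.
#' @return The rotated [ct_volume].
#' @export
rotate_volume <- function(volume, angles_deg, fill_hu = -1024) {
  a <- angles_deg * pi / 180
  rot_xy <- matrix(c(cos(a[1]), -sin(a[1]), 0,
                     sin(a[1]), cos(a[1]), 0,
                     0, 0, 1), 3, 3, byrow = TRUE)
  rot_xz <- matrix(c(cos(a[2]), 0, -sin(a[2]),
                     0, 1, 0,
                     sin(a[2]), 0, cos(a[2])), 3, 3, byrow = TRUE)
  rot_yz <- matrix(c(1, 0, 0,
                     0, cos(a[3]), -sin(a[3]),
                     0, sin(a[3]), cos(a[3])), 3, 3, byrow = TRUE)
  rot <- rot_xy %*% rot_xz %*% rot_yz
  d <- dim(volume$voxels)
  out <- rotate_resample_3d(as.vector(volume$voxels), d[1], d[2], d[3],
                            volume$spacing, t(rot), fill_hu)
  ct_volume(array(out, d), volume$spacing, volume$patient_id)
}

#' @export
print.swes_repeatability <- function(x, ...) {
  cat(sprintf("<swes_repeatability> %d pairs (%d skipped)\n",
              nrow(x$pairs), x$n_skipped))
  if (!is.null(x$bland_altman)) print(x$bland_altman)
  invisible(x)
}

#' Derive patient-level classification flags
#'
#' Adds `obstructed` (airway obstruction per the GOLD spirometric criterion,
#' FEV1/FVC strictly below 0.7) and `significant_emphysema` (sum-visual
#' strictly greater than 2) to a patient-record table. Both cutoffs are
#' strict inequalities: FEV1/FVC = 0.7 is not obstructed, sum-visual = 2 is
#' not significant emphysema.
#'
#' @param records Tibble with `fev1_fvc` and/or `sum_visual` columns.
#' @return The records with flag columns added/recomputed.
#' @export
label_patients <- function(records) {
  records <- as_tibble(records)
  if ("fev1_fvc" %in% names(records))
    records$obstructed <- records$fev1_fvc < 0.7
  if ("sum_visual" %in% names(records))
    records$significant_emphysema <- records$sum_visual > 2L
  records
}
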