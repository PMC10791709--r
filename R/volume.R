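#' CT volume and lung mask containers
#'
#' A `ct_volume` holds a 3-D grid of attenuation values in Hounsfield units
#' (HU) together with its physical voxel spacing; a `lung_mask` holds integer
#' labels on the same grid (0 = background, 1 = right lung, 2 = left lung).
#' The array axes are (x, y, z) with z the slice index, increasing cranially.
#'
#' On construction HU values are clamped to \[−1100, 3100\]; values outside
#' this range arise from air-calibration drift or corrupt voxels and would
#' otherwise distort densitometry. The number of clamped voxels is kept in
#' the `n_clamped` attribute.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing Numeric length-3 vector of voxel sizes in mm (x, y, z).
#' @param patient_id Optional identifier carried through the pipeline.
#' @return `ct_volume()` returns an object of class `ct_volume`;
#'   `lung_mask()` returns an object of class `lung_mask`.
#' @examples
#' vol <- ct_volume(array(-850, c(8, 8, 4)), spacing = c(0.7, 0.7, 0.6))
#' vol
#' @export
ct_volume <- function(voxels, spacing, patient_id = NA_character_) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three positive voxel sizes in mm.")
  if (dim(voxels)[3] < 1) abort("volume must contain at least one slice.")
  lo <- -1100; hi <- 3100
  n_clamped <- sum(voxels < lo | voxels > hi)
  if (n_clamped > 0) voxels[] <- pmin(pmax(voxels, lo), hi)
  structure(
    list(voxels = voxels, spacing = spacing,
         patient_id = as.character(patient_id)),
    n_clamped = n_clamped, class = "ct_volume")
}

#' @param labels 3-D integer array with values in {0, 1, 2}.
#' @rdname ct_volume
#' @export
lung_mask <- function(labels, spacing, patient_id = NA_character_) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    abort("`spacing` must be three positive voxel sizes in mm.")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:2))
    abort("mask labels must be 0 (background), 1 (right lung) or 2 (left lung).")
  structure(
    list(labels = labels, spacing = spacing,
         patient_id = as.character(patient_id)),
    class = "lung_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<lung_mask> %d x %d x %d voxels, right %d, left %d lung voxels\n",
    d[1], d[2], d[3], sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' @export
dim.lung_mask <- function(x) dim(x$labels)

check_paired_geometry <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$labels)))
    abort("volume and mask have different grid shapes.")
  if (max(abs(volume$spacing - mask$spacing)) > 1e-6)
    abort("volume and mask have different voxel spacings.")
  invisible(TRUE)
}
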