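#' Read a CT volume from NIfTI, MetaImage or a DICOM series directory
#'
#' Voxel values are returned in Hounsfield units: for DICOM the rescale
#' slope/intercept is applied and slices are ordered by their geometric z
#' position (file order is irrelevant); NIfTI and MetaImage values are taken
#' as stored. HU values outside \[−1100, 3100\] are clamped and counted in
#' the `n_clamped` attribute of the result.
#'
#' @param path A `.nii`/`.nii.gz`/`.mha`/`.mhd` file or a directory holding a
#'   single DICOM series.
#' @param patient_id Optional identifier to attach.
#' @return A [ct_volume].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path, patient_id = NA_character_) {
  raw <- read_volume_raw(path)
  ct_volume(raw$voxels, raw$spacing, patient_id)
}

#' @rdname read_volume
#' @return `read_mask()` returns a [lung_mask] with labels {0, 1, 2}.
#' @export
read_mask <- function(path, patient_id = NA_character_) {
  raw <- read_volume_raw(path)
  lung_mask(round(raw$voxels), raw$spacing, patient_id)
}

read_volume_raw <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    vox <- array(as.numeric(img), dim = dim(img))
    list(voxels = vox, spacing = as.numeric(RNifti::pixdim(img))[1:3])
  } else if (grepl("\\.(mha|mhd)$", lower)) {
    read_metaimage(path)
  } else {
    abort(sprintf("unsupported volume format: '%s'", basename(path)))
  }
}

#' Write a CT volume or lung mask
#'
#' The physical voxel spacing travels with the file (NIfTI pixdim, MetaImage
#' ElementSpacing, DICOM PixelSpacing + slice positions), so a write/read
#' round trip reproduces both voxels and geometry exactly.
#'
#' @param volume A [ct_volume] or [lung_mask].
#' @param path Output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`, `.mhd`) or a directory for a DICOM series.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "lung_mask")) {
    vox <- volume$labels
  } else if (inherits(volume, "ct_volume")) {
    vox <- volume$voxels
  } else abort("`volume` must be a ct_volume or lung_mask.")
  if (!dir.exists(dirname(path)))
    abort(sprintf("parent directory '%s' does not exist.", dirname(path)))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    nii <- RNifti::asNifti(vox)
    RNifti::pixdim(nii) <- volume$spacing
    RNifti::writeNifti(nii, path)
  } else if (grepl("\\.(mha|mhd)$", lower)) {
    write_metaimage(vox, volume$spacing, path)
  } else if (!grepl("\\.", basename(path))) {
    write_dicom_series(vox, volume$spacing, path,
                       patient_id = volume$patient_id)
  } else {
    abort(sprintf("unsupported volume format: '%s'", basename(path)))
  }
  invisible(path)
}

patient_table_cols <- c("patient_id", "swes", "lav950", "sum_visual",
                        "fev1_fvc", "dlco_pred_pct")

#' Read and validate a per-patient score table
#'
#' Expects a CSV with header columns `patient_id`, `swes`, `lav950`,
#' `sum_visual`, `fev1_fvc`, `dlco_pred_pct`. The diffusing-capacity column
#' may contain empty cells (DLco is not measured in every participant);
#' every other field is required. `sum_visual` is the sum of six regional
#' grades 0–3 and must lie in 0–18; `lav950` is a fraction in \[0, 1\].
#'
#' @param path CSV file path.
#' @return A tibble with one row per patient, flags added via
#'   [label_patients()].
#' @export
read_patient_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(setdiff(patient_table_cols, "dlco_pred_pct"),
                          names(tab))
  if (length(missing_cols) > 0)
    abort(paste0("patient table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  if (!"dlco_pred_pct" %in% names(tab)) tab$dlco_pred_pct <- NA_real_
  tab <- dplyr::mutate(
    tab,
    patient_id = as.character(.data$patient_id),
    swes = as.numeric(.data$swes),
    lav950 = as.numeric(.data$lav950),
    sum_visual = as.integer(.data$sum_visual),
    fev1_fvc = as.numeric(.data$fev1_fvc),
    dlco_pred_pct = as.numeric(.data$dlco_pred_pct))
  bad <- !is.na(tab$sum_visual) &
    (tab$sum_visual < 0L | tab$sum_visual > 18L)
  if (any(bad))
    abort(sprintf(
      "sum_visual outside the 0-18 scale for patient(s): %s",
      paste(tab$patient_id[bad], collapse = ", ")))
  if (any(tab$lav950 < 0 | tab$lav950 > 1, na.rm = TRUE))
    abort("lav950 must be a fraction in [0, 1].")
  if (any(tab$swes < 0, na.rm = TRUE)) abort("swes must be non-negative.")
  label_patients(as_tibble(tab[, patient_table_cols]))
}

#' @param records A patient-record tibble.
#' @rdname read_patient_table
#' @export
write_patient_table <- function(records, path) {
  readr::write_csv(records[, intersect(patient_table_cols, names(records))],
                   path)
  invisible(path)
}

#' Read or write a per-slice annotation table
#'
#' The annotation CSV schema is `patient_id`, `side` (`left`/`right`),
#' `slice_index` (0-based), `scale` (`four_degree` or `ten_degree`), `label`.
#'
#' @param path CSV file path.
#' @return A slice-track tibble (see [blocks_to_slices()]).
#' @export
read_annotations <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "side", "slice_index", "scale", "label")
  if (!all(need %in% names(tab)))
    abort(paste0("annotation table needs columns: ",
                 paste(need, collapse = ", ")))
  scale <- unique(tab$scale)
  if (length(scale) != 1)
    abort("annotation table mixes label scales.")
  new_slice_track(
    tibble(patient_id = as.character(tab$patient_id),
           side = as.character(tab$side),
           slice_index = as.integer(tab$slice_index),
           label = as.numeric(tab$label)),
    scale = scale)
}

#' @param track A slice-track tibble.
#' @rdname read_annotations
#' @export
write_annotations <- function(track, path) {
  out <- tibble(
    patient_id = track$patient_id %||% NA_character_,
    side = track$side,
    slice_index = track$slice_index,
    scale = track_scale(track),
    label = track$label)
  readr::write_csv(out, path)
  invisible(path)
}
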