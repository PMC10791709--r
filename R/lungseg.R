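#' Densitometric left/right lung segmentation
#'
#' Standard threshold-based lung extraction: voxels below −320 HU are
#' candidate air; connected components (6-connectivity) touching the
#' in-plane image border are discarded as external air; the two largest
#' remaining components are taken as the lungs, assigned left/right by their
#' centroid x position relative to the volume midline; a morphological
#' closing (ball radius 2 voxels) fills vessels. If only one non-border
#' component remains (fused lungs) it is split at the per-slice midline with
#' a warning. Deterministic; no RNG. Tracheal air is not removed, which at
#' phantom scale is irrelevant but is a small bias source on real data.
#'
#' @param volume A [ct_volume] in HU.
#' @param threshold_hu Air/parenchyma threshold, HU.
#' @param closing_radius Ball radius (voxels) of the vessel-filling closing.
#' @return A [lung_mask] (0 background, 1 right, 2 left).
#' @export
segment_lungs <- function(volume, threshold_hu = -320, closing_radius = 2) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  cand <- volume$voxels < threshold_hu
  if (!any(cand)) abort("lungs not found: no voxels below the air threshold.")
  lab <- cc_label_3d(as.vector(cand), d[1], d[2], d[3])
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ]))
  border <- border[border != 0L]
  counts <- tabulate(lab)
  keep <- setdiff(which(counts > 0), border)
  if (length(keep) == 0) abort("lungs not found: all air touches the border.")
  keep <- keep[order(counts[keep], decreasing = TRUE)]
  mid <- (d[1] + 1) / 2
  labels <- array(0L, d)
  if (length(keep) == 1) {
    warn("single fused lung component; splitting at the volume midline.")
    comp <- lab == keep[1]
    xi <- slice.index(comp, 1)
    labels[comp & xi <= mid] <- 1L
    labels[comp & xi > mid] <- 2L
  } else {
    two <- keep[1:2]
    cx <- vapply(two, function(id)
      mean(slice.index(lab, 1)[lab == id]), numeric(1))
    right_id <- two[which.min(cx)]
    left_id <- two[which.max(cx)]
    labels[lab == right_id] <- 1L
    labels[lab == left_id] <- 2L
  }
  if (closing_radius > 0) {
    for (side in 1:2) {
      m <- labels == side
      closed <- erode_ball_3d(
        dilate_ball_3d(as.vector(m), d[1], d[2], d[3], closing_radius),
        d[1], d[2], d[3], closing_radius)
      add <- array(closed, d) & labels == 0L
      labels[add] <- as.integer(side)
    }
  }
  lung_mask(labels, volume$spacing, volume$patient_id)
}

#' Per-slice segmented lung areas
#'
#' The SWES aggregation weights each slice-lung prediction by its segmented
#' lung area; this computes those areas exactly as in-plane voxel count times
#' in-plane voxel dimensions. Every slice appears for both sides, with zero
#' area where no lung is present.
#'
#' @param mask A [lung_mask].
#' @return A tibble with `slice_index` (0-based), `side`, `area_mm2`.
#' @examples
#' m <- lung_mask(array(c(rep(1L, 8), rep(0L, 56)), c(4, 4, 4)),
#'                spacing = c(0.7, 0.7, 0.6))
#' slice_areas(m)
#' @export
slice_areas <- function(mask) {
  stopifnot(inherits(mask, "lung_mask"))
  d <- dim(mask$labels)
  px_area <- mask$spacing[1] * mask$spacing[2]
  counts_right <- apply(mask$labels == 1L, 3, sum)
  counts_left <- apply(mask$labels == 2L, 3, sum)
  tibble(
    patient_id = mask$patient_id,
    slice_index = rep(seq_len(d[3]) - 1L, 2L),
    side = rep(c("right", "left"), each = d[3]),
    area_mm2 = c(counts_right, counts_left) * px_area)
}
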