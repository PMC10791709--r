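#' Slice label tracks
#'
#' A slice track is a tibble with one row per (slice, lung side) carrying an
#' emphysema label, either on the ordinal 4-degree reader scale (integers
#' 0–3, with a `block` column tying slices to their 1-cm annotation block) or
#' on the continuous 10-degree training scale (reals in \[0, 10\]). The scale
#' is carried in the `track_scale()` attribute.
#'
#' @param df Tibble with columns `side`, `slice_index` (0-based), `label`
#'   (and optionally `patient_id`, `block`).
#' @param scale `"four_degree"` or `"ten_degree"`.
#' @return A `slice_track` tibble.
#' @export
new_slice_track <- function(df, scale = c("ten_degree", "four_degree")) {
  scale <- match.arg(scale)
  df <- as_tibble(df)
  stopifnot(all(c("side", "slice_index", "label") %in% names(df)))
  if (scale == "four_degree") {
    if (!all(df$label %in% 0:3))
      abort("four_degree labels must be integers 0-3.")
  } else if (any(df$label < 0 | df$label > 10)) {
    abort("ten_degree labels must lie in [0, 10].")
  }
  structure(df, scale = scale, class = c("slice_track", class(df)))
}

#' @param track A slice track.
#' @rdname new_slice_track
#' @export
track_scale <- function(track) attr(track, "scale")

track_groups <- function(track) {
  g <- intersect(c("patient_id", "side"), names(track))
  dplyr::grouped_df(track, g)
}

rebuild_track <- function(df, scale) {
  new_slice_track(dplyr::ungroup(df), scale = scale)
}

#' Expand per-centimeter 4-degree grades to per-slice labels
#'
#' Each lung is annotated per centimeter of z-extent on a 4-degree emphysema
#' scale (0 none, 1 mild, 2 moderate, 3 severe). A centimeter block spans
#' `ceiling(10 / z_spacing_mm)` slices; every slice inherits its block's
#' grade, and a final partial block is covered by its own grade.
#'
#' @param cm_grades Ordered integer grades in 0–3, one per centimeter block,
#'   caudal to cranial.
#' @param z_spacing_mm Slice spacing in mm.
#' @param side `"left"` or `"right"`.
#' @param n_slices Total slice count; defaults to full blocks, a smaller
#'   value truncates the last block (partial centimeter).
#' @param patient_id Optional identifier.
#' @return A 4-degree `slice_track` with a `block` column.
#' @examples
#' blocks_to_slices(c(0, 3), z_spacing_mm = 1.0)
#' @export
blocks_to_slices <- function(cm_grades, z_spacing_mm, side = "right",
                             n_slices = NULL, patient_id = NA_character_) {
  if (length(cm_grades) == 0) abort("at least one centimeter grade is needed.")
  if (!all(cm_grades %in% 0:3)) abort("centimeter grades must be in 0-3.")
  if (z_spacing_mm <= 0) abort("z spacing must be positive.")
  per_block <- ceiling(10 / z_spacing_mm)
  labels <- rep(as.integer(cm_grades), each = per_block)
  blocks <- rep(seq_along(cm_grades), each = per_block)
  if (!is.null(n_slices)) {
    if (n_slices > length(labels))
      abort("n_slices exceeds the extent covered by the grades.")
    labels <- labels[seq_len(n_slices)]
    blocks <- blocks[seq_len(n_slices)]
  }
  new_slice_track(
    tibble(patient_id = patient_id, side = side,
           slice_index = seq_along(labels) - 1L,
           block = blocks, label = labels),
    scale = "four_degree")
}

#' Median z-direction filtering of 4-degree annotations
#'
#' Replaces each centimeter block's grade by the median of the grades in a
#' window of `window_blocks` blocks centered on it. At the track ends the
#' window shrinks symmetrically (so the outermost blocks are kept as-is and
#' the filter output stays on the 4-degree scale). By default the filter is
#' applied repeatedly until the track no longer changes, i.e. until it is a
#' root signal of the filter; this makes the operation idempotent.
#'
#' @param track A 4-degree `slice_track` (see [blocks_to_slices()]).
#' @param window_blocks Odd window width in blocks.
#' @param iterate Apply passes until convergence (default) or a single pass.
#' @return A filtered 4-degree `slice_track`.
#' @examples
#' tr <- blocks_to_slices(c(0, 0, 3, 0, 0), z_spacing_mm = 5)
#' unique(median_z_filter(tr)$label)
#' @export
median_z_filter <- function(track, window_blocks = 3, iterate = TRUE) {
  if (!identical(track_scale(track), "four_degree"))
    abort("median_z_filter expects a four_degree track.")
  if (window_blocks %% 2 != 1) abort("`window_blocks` must be odd.")
  h <- (window_blocks - 1) / 2
  out <- dplyr::group_modify(track_groups(track), function(df, key) {
    df <- dplyr::arrange(df, .data$slice_index)
    grades <- block_grades(df)
    passes <- 0L
    repeat {
      filtered <- median_pass(grades, h)
      passes <- passes + 1L
      if (!iterate || identical(filtered, grades) ||
          passes > length(grades)) break
      grades <- filtered
    }
    df$label <- filtered[match(df$block, sort(unique(df$block)))]
    df
  })
  rebuild_track(out, "four_degree")
}

block_grades <- function(df) {
  blocks <- sort(unique(df$block))
  vapply(blocks, function(b) as.integer(df$label[df$block == b][1]),
         integer(1))
}

median_pass <- function(grades, h) {
  nb <- length(grades)
  vapply(seq_len(nb), function(i) {
    r <- min(h, i - 1, nb - i)
    as.integer(median(grades[(i - r):(i + r)]))
  }, integer(1))
}

#' Refine 4-degree block annotations to a continuous 10-degree scale
#'
#' Increases label granularity from the 4-degree reader scale to 10 degrees:
#' block grades are mapped to anchor values 0, 10/3, 20/3, 10, anchors are
#' placed at the z center of each block, and a piecewise-linear interpolation
#' of the anchors is evaluated at every slice (constant beyond the outermost
#' block centers), clamped to \[0, 10\]. Deterministic; a reader-free
#' surrogate for refinement by inter-reader image comparison.
#'
#' @param track A (typically median-filtered) 4-degree `slice_track`.
#' @return A 10-degree `slice_track` on the same slices.
#' @examples
#' tr <- blocks_to_slices(c(1, 2), z_spacing_mm = 1)
#' range(refine_to_ten(tr)$label)
#' @export
refine_to_ten <- function(track) {
  if (!identical(track_scale(track), "four_degree"))
    abort("refine_to_ten expects a four_degree track.")
  out <- dplyr::group_modify(track_groups(track), function(df, key) {
    df <- dplyr::arrange(df, .data$slice_index)
    blocks <- sort(unique(df$block))
    anchors <- block_grades(df) * (10 / 3)
    centers <- vapply(blocks, function(b)
      mean(df$slice_index[df$block == b]), numeric(1))
    df$label <- if (length(blocks) == 1) rep(anchors, nrow(df)) else
      stats::approx(centers, anchors, xout = df$slice_index, rule = 2)$y
    df$label <- pmin(pmax(df$label, 0), 10)
    df$block <- NULL
    df
  })
  rebuild_track(out, "ten_degree")
}
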