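#' Tidy methods for swescore result objects
#'
#' One-row (or per-curve-point) tibbles in the broom style for the
#' statistical result classes.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name swescore-tidiers
NULL

#' @rdname swescore-tidiers
#' @export
tidy.pearson_cor <- function(x, ...) {
  tibble(estimate = x$r, statistic = x$statistic, p.value = x$p_value,
         n = x$n)
}

#' @rdname swescore-tidiers
#' @export
tidy.meng_test <- function(x, ...) {
  tibble(r_xy = x$r_xy, r_zy = x$r_zy, r_xz = x$r_xz,
         statistic = x$z_stat, p.value = x$p_value, n = x$n,
         alternative = x$alternative)
}

#' @rdname swescore-tidiers
#' @export
tidy.delong_test <- function(x, ...) {
  tibble(auc_a = x$auc_a, auc_b = x$auc_b, estimate = x$auc_a - x$auc_b,
         statistic = x$z_stat, p.value = x$p_value, n = x$n)
}

#' @rdname swescore-tidiers
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname swescore-tidiers
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname swescore-tidiers
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' @rdname swescore-tidiers
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
         loa_high = x$loa_high, n = x$n)
}

#' @rdname swescore-tidiers
#' @export
tidy.swes_repeatability <- function(x, ...) x$pairs

#' @rdname swescore-tidiers
#' @export
glance.swes_repeatability <- function(x, ...) {
  ba <- x$bland_altman
  tibble(n_pairs = nrow(x$pairs), n_skipped = x$n_skipped,
         bias = ba$bias %||% NA_real_, sd_diff = ba$sd_diff %||% NA_real_,
         loa_low = ba$loa_low %||% NA_real_,
         loa_high = ba$loa_high %||% NA_real_)
}
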