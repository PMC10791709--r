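#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform
#' `t = r * sqrt((n-2)/(1-r^2))` with n − 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @return A `pearson_cor` list with `r`, `p_value`, `n`, `statistic`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: correlation undefined.")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = n,
                 statistic = unname(ct$statistic)),
            class = "pearson_cor")
}

#' Meng's test for two dependent correlations sharing a criterion
#'
#' Compares r(x, y) with r(z, y) when x and z are measured on the same
#' subjects (overlapping dependent correlations). The z statistic is the
#' Fisher-z difference scaled by `sqrt((n-3) / (2 (1 - r_xz) h))` with
#' `h = (1 - f rbar2) / (1 - rbar2)`,
#' `f = min(1, (1 - r_xz) / (2 (1 - rbar2)))` and
#' `rbar2 = (r_xy^2 + r_zy^2) / 2`; the cap f <= 1 prevents a negative h at
#' extreme correlation patterns. Positive z means x correlates more strongly
#' with the criterion than z does.
#'
#' @param x,z Competing predictor vectors.
#' @param y Criterion vector.
#' @param alternative `"two.sided"` (default) or `"one.sided"` (stronger
#'   correlation for x).
#' @param r_xy,r_zy,r_xz,n Alternatively, precomputed correlations and the
#'   sample size instead of raw data.
#' @return A `meng_test` list with the three correlations, `n`, `z_stat` and
#'   `p_value`.
#' @export
meng_test <- function(x = NULL, z = NULL, y = NULL,
                      alternative = c("two.sided", "one.sided"),
                      r_xy = NULL, r_zy = NULL, r_xz = NULL, n = NULL) {
  alternative <- match.arg(alternative)
  if (is.null(r_xy)) {
    if (is.null(x) || is.null(z) || is.null(y))
      abort("supply x, z, y or precomputed correlations.")
    if (length(unique(c(length(x), length(z), length(y)))) != 1)
      abort("x, z, y must have equal length.")
    ok <- stats::complete.cases(x, z, y)
    x <- x[ok]; z <- z[ok]; y <- y[ok]
    n <- length(x)
    r_xy <- cor(x, y); r_zy <- cor(z, y); r_xz <- cor(x, z)
  }
  if (n < 4) abort("Meng's test needs n >= 4.")
  if (abs(r_xz) >= 1) abort("predictors are perfectly correlated; test degenerate.")
  rbar2 <- (r_xy^2 + r_zy^2) / 2
  f <- min(1, (1 - r_xz) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z_stat <- (atanh(r_xy) - atanh(r_zy)) *
    sqrt((n - 3) / (2 * (1 - r_xz) * h))
  p <- if (alternative == "two.sided") 2 * pnorm(-abs(z_stat))
       else pnorm(-z_stat)
  structure(list(r_xy = r_xy, r_zy = r_zy, r_xz = r_xz, n = n,
                 z_stat = z_stat, p_value = min(p, 1),
                 alternative = alternative),
            class = "meng_test")
}

auc_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  u <- sort(unique(labels))
  if (length(u) != 2) abort("labels must contain exactly two classes.")
  labels == u[2]
}

#' Area under the ROC curve
#'
#' Mann–Whitney estimator: the probability that a random positive outscores
#' a random negative, ties counting one half. Computed from midranks.
#'
#' @param scores Numeric scores, larger meaning more likely positive.
#' @param labels Two-class labels (logical, or any two-level vector whose
#'   larger/second level is the positive class).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  pos <- auc_labels(labels)
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) abort("both classes must be present.")
  r <- rank(scores)
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

# Placement values: for each positive, the fraction of negatives it beats
# (ties half); for each negative, the fraction of positives it undercuts.
placements <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  v10 <- vapply(sp, function(s) mean((s > sn) + 0.5 * (s == sn)), 0)
  v01 <- vapply(sn, function(s) mean((sp > s) + 0.5 * (sp == s)), 0)
  list(v10 = v10, v01 = v01)
}

#' DeLong's test for paired ROC curves
#'
#' Nonparametric comparison of two AUCs measured on the same subjects, via
#' the structural-components (placement-value) covariance estimate. The
#' statistic is `z = (auc_a - auc_b) / se` with a two-sided normal p-value;
#' swapping the score vectors negates z and leaves p unchanged.
#'
#' @param scores_a,scores_b Paired score vectors on identical subjects.
#' @param labels Two-class labels (both classes present).
#' @return A `delong_test` list with `auc_a`, `auc_b`, `z_stat`, `p_value`,
#'   `se` and `n`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    abort("scores and labels must have equal length.")
  pos <- auc_labels(labels)
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) abort("both classes must be present.")
  if (m < 2 || n < 2)
    abort("DeLong's covariance needs at least 2 subjects in each class.")
  pa <- placements(scores_a, pos)
  pb <- placements(scores_b, pos)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= .Machine$double.eps) {
    if (abs(auc_a - auc_b) < 1e-12) {
      z_stat <- 0; p <- 1; se <- 0
    } else {
      abort("zero variance of the AUC difference with unequal AUCs.")
    }
  } else {
    se <- sqrt(var_diff)
    z_stat <- (auc_a - auc_b) / se
    p <- 2 * pnorm(-abs(z_stat))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, z_stat = z_stat,
                 p_value = p, se = se, n = length(labels)),
            class = "delong_test")
}

#' Percentile bootstrap confidence interval
#'
#' Resamples subjects (rows for data frames, elements for vectors) with
#' replacement and returns the percentile interval of the statistic over
#' `n_boot` resamples. If the statistic is undefined on a resample (for
#' example a single-class ROC sample), that resample is redrawn; the number
#' of redraws is recorded in the `n_redrawn` attribute. Deterministic for a
#' fixed seed.
#'
#' @param data Vector or data frame of per-subject data.
#' @param statistic Function of a resampled `data` returning a scalar.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed RNG seed.
#' @return Named numeric `c(low, high)` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 2000, level = 0.95,
                         seed = 1L) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 2) abort("need at least 2 subjects to bootstrap.")
  take <- if (is.data.frame(data)) function(i) data[i, , drop = FALSE]
          else function(i) data[i]
  with_seed(seed, {
    stats_v <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        val <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 50L * n_boot)
          abort("statistic undefined on virtually every resample.")
      }
      stats_v[b] <- val
    }
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(stats_v, c(alpha, 1 - alpha), type = 7))
    structure(c(low = ci[1], high = ci[2]), n_redrawn = n_redrawn)
  })
}

#' ROC analysis with bootstrap confidence interval
#'
#' AUC by the Mann–Whitney estimator, a 95% (by default) percentile
#' bootstrap CI with subject-level resampling, and the ROC curve points.
#'
#' @inheritParams auc
#' @param n_boot Bootstrap resamples for the CI.
#' @param level Confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return A `roc_result` with `auc`, `ci_low`, `ci_high`, and `curve` (a
#'   tibble of (fpr, tpr) from (0,0) to (1,1)).
#' @export
roc_curve <- function(scores, labels, n_boot = 2000, level = 0.95,
                      seed = 1L) {
  pos <- auc_labels(labels)
  a <- auc(scores, pos)
  df <- tibble(score = scores, pos = pos)
  ci <- bootstrap_ci(df, function(d) auc(d$score, d$pos),
                     n_boot = n_boot, level = level, seed = seed)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- purrr::map_dfr(thr, function(t)
    tibble(threshold = t,
           fpr = mean(scores[!pos] >= t),
           tpr = mean(scores[pos] >= t)))
  structure(list(auc = a, ci_low = unname(ci["low"]),
                 ci_high = unname(ci["high"]), curve = curve,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_result")
}

#' Bland–Altman agreement between paired measurements
#'
#' Differences are `a - b`; the bias is their mean, the standard deviation
#' uses the n − 1 denominator, and the limits of agreement are
#' bias ± 1.96 SD.
#'
#' @param a,b Paired numeric vectors, n >= 2.
#' @return A `bland_altman` list with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n` and the per-pair tibble `data`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) abort("a and b must have equal length.")
  if (length(a) < 2) abort("need at least 2 pairs.")
  d <- a - b
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 n = length(d),
                 data = tibble(mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.pearson_cor <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.3g)\n", x$r, x$n, x$p_value))
  invisible(x)
}

#' @export
print.meng_test <- function(x, ...) {
  cat(sprintf(
    "Meng's test: r_xy = %.3f vs r_zy = %.3f (r_xz = %.3f, n = %d)\n  z = %.3f, p = %.3g (%s)\n",
    x$r_xy, x$r_zy, x$r_xz, x$n, x$z_stat, x$p_value, x$alternative))
  invisible(x)
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf(
    "DeLong's test: AUC %.3f vs %.3f, z = %.3f, p = %.3g (n = %d)\n",
    x$auc_a, x$auc_b, x$z_stat, x$p_value, x$n))
  invisible(x)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.4f, SD %.4f, LoA [%.4f, %.4f] (n = %d)\n",
    x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}
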