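#' Validate emphysema scores against reference tests in a cohort
#'
#' Produces the standard validation report for a patient-record table:
#' pairwise Meng comparisons of the correlations of SWES, LAV950 and
#' sum-visual with each criterion (FEV1/FVC, and DLcoPred% where available),
#' and ROC analyses of SWES and LAV950 (plus sum-visual for obstruction)
#' against the two clinical endpoints — significant visual emphysema
#' (sum-visual > 2) and airway obstruction (FEV1/FVC < 0.7) — with bootstrap
#' CIs and DeLong comparisons. Endpoints with a single class are skipped
#' with a warning.
#'
#' @param records Patient-record tibble with `swes`, `lav950`, `sum_visual`,
#'   `fev1_fvc` and optionally `dlco_pred_pct` (>= 10 rows).
#' @param n_boot Bootstrap resamples for ROC CIs.
#' @param seed RNG seed for the bootstrap.
#' @return A `cohort_validation`: list of tibbles `correlations` (one row
#'   per predictor pair and criterion: both correlations, r between the
#'   predictors, Meng z and p), `rocs` (AUC and CI per score and endpoint)
#'   and `roc_comparisons` (DeLong tests), plus `n`.
#' @export
validate_cohort <- function(records, n_boot = 2000, seed = 1L) {
  records <- label_patients(records)
  if (nrow(records) < 10) abort("need at least 10 records to validate.")
  scores <- c("swes", "lav950", "sum_visual")
  criteria <- c("fev1_fvc",
                if ("dlco_pred_pct" %in% names(records) &&
                    sum(!is.na(records$dlco_pred_pct)) >= 10) "dlco_pred_pct")
  pairs <- list(c("swes", "lav950"), c("swes", "sum_visual"),
                c("lav950", "sum_visual"))
  correlations <- purrr::map_dfr(criteria, function(crit) {
    purrr::map_dfr(pairs, function(pr) {
      ok <- stats::complete.cases(records[[pr[1]]], records[[pr[2]]],
                                  records[[crit]])
      mt <- meng_test(records[[pr[1]]][ok], records[[pr[2]]][ok],
                      records[[crit]][ok])
      tibble(criterion = crit, predictor_a = pr[1], predictor_b = pr[2],
             r_a = mt$r_xy, r_b = mt$r_zy, r_ab = mt$r_xz, n = mt$n,
             z = mt$z_stat, p_value = mt$p_value)
    })
  })
  endpoints <- list(
    significant_emphysema = records$significant_emphysema,
    obstructed = records$obstructed)
  roc_scores <- list(significant_emphysema = c("swes", "lav950"),
                     obstructed = scores)
  rocs <- list(); comparisons <- list(); roc_objects <- list()
  for (ep in names(endpoints)) {
    lab <- endpoints[[ep]]
    tab <- table(lab[!is.na(lab)])
    if (length(tab) < 2 || min(tab) < 2) {
      warn(sprintf(
        "endpoint '%s' lacks 2 subjects in each class; ROC skipped.", ep))
      next
    }
    for (sc in roc_scores[[ep]]) {
      rr <- roc_curve(records[[sc]], lab, n_boot = n_boot, seed = seed)
      roc_objects[[paste(ep, sc, sep = ".")]] <- rr
      rocs[[length(rocs) + 1L]] <- tibble(
        endpoint = ep, score = sc, auc = rr$auc,
        ci_low = rr$ci_low, ci_high = rr$ci_high)
    }
    for (pr in utils::combn(roc_scores[[ep]], 2, simplify = FALSE)) {
      dl <- delong_test(records[[pr[1]]], records[[pr[2]]], lab)
      comparisons[[length(comparisons) + 1L]] <- tibble(
        endpoint = ep, score_a = pr[1], score_b = pr[2],
        auc_a = dl$auc_a, auc_b = dl$auc_b, z = dl$z_stat,
        p_value = dl$p_value)
    }
  }
  structure(
    list(correlations = correlations,
         rocs = dplyr::bind_rows(rocs),
         roc_comparisons = dplyr::bind_rows(comparisons),
         roc_objects = roc_objects,
         n = nrow(records)),
    class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat(sprintf("<cohort_validation> n = %d patients\n\n", x$n))
  cat("Correlation comparisons (Meng's test):\n")
  print(as.data.frame(x$correlations), digits = 3, row.names = FALSE)
  if (nrow(x$rocs)) {
    cat("\nROC analyses:\n")
    print(as.data.frame(x$rocs), digits = 3, row.names = FALSE)
    cat("\nPaired AUC comparisons (DeLong's test):\n")
    print(as.data.frame(x$roc_comparisons), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Write a validation report to CSV files
#'
#' Writes `correlations.csv`, `roc.csv`, `roc_comparisons.csv` and a
#' plain-text `summary.txt` under `dir`.
#'
#' @param validation A [validate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_validation <- function(validation, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(validation$correlations, file.path(dir, "correlations.csv"))
  readr::write_csv(validation$rocs, file.path(dir, "roc.csv"))
  readr::write_csv(validation$roc_comparisons,
                   file.path(dir, "roc_comparisons.csv"))
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); print(validation); sink()
  close(con)
  invisible(dir)
}
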