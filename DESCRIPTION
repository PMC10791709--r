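Package: swescore
Title: Slice-Wise Whole-Lung CT Emphysema Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative emphysema scoring for thin-slice chest CT. Implements
    the slice-wise whole-lung emphysema score (SWES): per-slice, per-lung
    emphysema severity is predicted on a 0-10 scale by a residual
    convolutional regression network and aggregated into a patient score as a
    lung-area-weighted mean. Includes densitometric lung segmentation, the
    LAV950 low-attenuation baseline, a three-step annotation refinement
    pipeline (per-centimeter 4-degree grades, median z-filtering, 10-degree
    interpolation), an intra-scan rotation repeatability harness, synthetic CT
    phantom and cohort simulation with known ground truth, and the validation
    statistics used to compare emphysema scores: Pearson correlations, Meng's
    test for dependent correlations, ROC/AUC with bootstrap confidence
    intervals, DeLong's paired test, and Bland-Altman agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
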