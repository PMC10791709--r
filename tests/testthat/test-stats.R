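test_that("pearson_r matches hand computation and cor.test", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  pr <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(pr$r, 0.8)
  ct <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(pr$p_value, ct$p.value)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("Meng's test closed form, null, and antisymmetry", {
  # independent transcription of the closed form at fixed correlations
  r_xy <- 0.6; r_zy <- 0.3; r_xz <- 0.5; n <- 100
  rbar2 <- (r_xy^2 + r_zy^2) / 2
  f <- min(1, (1 - r_xz) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z_oracle <- (atanh(r_xy) - atanh(r_zy)) *
    sqrt((n - 3) / (2 * (1 - r_xz) * h))
  mt <- meng_test(r_xy = r_xy, r_zy = r_zy, r_xz = r_xz, n = n)
  expect_equal(mt$z_stat, z_oracle)
  expect_equal(mt$p_value, 2 * pnorm(-abs(z_oracle)))

  with_seed_test(2, {
    x <- rnorm(50); y <- 0.5 * x + rnorm(50); z <- 0.3 * y + rnorm(50)
    ab <- meng_test(x, z, y)
    ba <- meng_test(z, x, y)
    expect_equal(ba$z_stat, -ab$z_stat)
    expect_equal(ba$p_value, ab$p_value)
    # perfectly correlated predictors are degenerate
    expect_error(meng_test(x, x, y), "degenerate")
  })
  dup <- meng_test(r_xy = 0.4, r_zy = 0.4, r_xz = 0.8, n = 50)
  expect_equal(dup$z_stat, 0)
  expect_equal(dup$p_value, 1)
})

test_that("Meng's z matches a trivariate-normal Monte-Carlo at stated parameters", {
  # at r_xy=0.6, r_zy=0.3, r_xz=0.5, n=100 the test should reject a fair
  # fraction of the time; compare the closed form against the empirical
  # rejection rate of simulated data with those population correlations
  Sig <- matrix(c(1, 0.5, 0.6,
                  0.5, 1, 0.3,
                  0.6, 0.3, 1), 3, 3)
  L <- chol(Sig)
  n <- 50
  z_closed <- meng_test(r_xy = 0.6, r_zy = 0.3, r_xz = 0.5, n = n)$z_stat
  with_seed_test(77, {
    z_all <- replicate(5000, {
      m <- matrix(rnorm(3 * n), n) %*% L
      meng_test(m[, 1], m[, 2], m[, 3])$z_stat
    })
    # the empirical z should center near the closed form with unit spread
    # (Fisher-z variance stabilization)
    expect_lt(abs(mean(z_all) - z_closed), 0.3)
    expect_lt(abs(sd(z_all) - 1), 0.2)
  })
})

test_that("AUC equals brute-force pair counting, including ties", {
  expect_equal(swescore::auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_equal(swescore::auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(swescore::auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  with_seed_test(12, {
    for (i in 1:200) {
      n <- sample(4:30, 1)
      s <- sample(0:6, n, replace = TRUE) + sample(c(0, 0.5), n, TRUE)
      l <- runif(n) < 0.5
      if (length(unique(l)) < 2) next
      brute <- mean(outer(s[l], s[!l],
                          function(a, b) (a > b) + 0.5 * (a == b)))
      expect_identical(swescore::auc(s, l), brute)
    }
  })
  expect_error(swescore::auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with pROC on random instances", {
  with_seed_test(4, {
    for (i in 1:20) {
      s <- rnorm(40); l <- runif(40) < 0.4
      if (length(unique(l)) < 2) next
      pr <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                           direction = "<")))
      expect_equal(swescore::auc(s, l), pr)
    }
  })
})

test_that("DeLong variance matches a brute-force placement oracle", {
  scores_a <- c(0.9, 0.8, 0.35, 0.7, 0.2, 0.6, 0.5, 0.4, 0.3, 0.1)
  scores_b <- c(0.7, 0.2, 0.9, 0.4, 0.5, 0.1, 0.6, 0.8, 0.3, 0.35)
  labels <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
              FALSE)
  dl <- delong_test(scores_a, scores_b, labels)
  # brute-force placement values and their empirical covariances
  pv <- function(s) {
    sp <- s[labels]; sn <- s[!labels]
    v10 <- sapply(sp, function(x) mean((x > sn) + 0.5 * (x == sn)))
    v01 <- sapply(sn, function(x) mean((sp > x) + 0.5 * (sp == x)))
    list(v10 = v10, v01 = v01)
  }
  a <- pv(scores_a); b <- pv(scores_b)
  var_oracle <- (var(a$v10) + var(b$v10) - 2 * cov(a$v10, b$v10)) / 4 +
    (var(a$v01) + var(b$v01) - 2 * cov(a$v01, b$v01)) / 6
  expect_equal(dl$se^2, var_oracle)
  expect_equal(dl$auc_a, mean(a$v10))
  # antisymmetry
  rev_dl <- delong_test(scores_b, scores_a, labels)
  expect_equal(rev_dl$z_stat, -dl$z_stat)
  expect_equal(rev_dl$p_value, dl$p_value)
  # identical scores: exact null
  same <- delong_test(scores_a, scores_a, labels)
  expect_equal(same$z_stat, 0)
  expect_equal(same$p_value, 1)
})

test_that("DeLong agrees with pROC's paired test", {
  with_seed_test(9, {
    l <- rep(c(TRUE, FALSE), c(25, 35))
    s1 <- rnorm(60) + l
    s2 <- 0.5 * s1 + rnorm(60)
    dl <- delong_test(s1, s2, l)
    rt <- pROC::roc.test(pROC::roc(l, s1, quiet = TRUE, direction = "<"),
                         pROC::roc(l, s2, quiet = TRUE, direction = "<"),
                         method = "delong", paired = TRUE)
    expect_equal(dl$z_stat, unname(rt$statistic))
    expect_equal(dl$p_value, rt$p.value)
  })
})

test_that("bootstrap CIs are seeded, subject-level, and sane on constants", {
  const <- rep(3.2, 20)
  ci <- bootstrap_ci(const, mean, n_boot = 100, seed = 1)
  expect_equal(unname(ci["low"]), 3.2)
  expect_equal(unname(ci["high"]), 3.2)
  with_seed_test(5, {
    x <- rnorm(100)
    a <- bootstrap_ci(x, mean, n_boot = 500, seed = 7)
    b <- bootstrap_ci(x, mean, n_boot = 500, seed = 7)
    expect_identical(a, b)
  })
})

test_that("bootstrap CI width approximates the analytic normal interval", {
  # mean of n = 100 standard normals: analytic 95% width 2 * 1.96 / 10
  with_seed_test(6, {
    widths <- replicate(200, {
      x <- rnorm(100)
      ci <- bootstrap_ci(x, mean, n_boot = 400, seed = sample.int(1e6, 1))
      ci["high"] - ci["low"]
    })
    expect_lt(abs(mean(widths) - 2 * 1.96 / 10) / (2 * 1.96 / 10), 0.25)
  })
})

test_that("bootstrap redraws resamples on which the statistic is undefined", {
  df <- data.frame(score = rnorm(12), pos = rep(c(TRUE, FALSE), c(2, 10)))
  ci <- bootstrap_ci(df, function(d) swescore::auc(d$score, d$pos),
                     n_boot = 200, seed = 3)
  expect_true(is.finite(ci["low"]) && is.finite(ci["high"]))
  expect_gte(attr(ci, "n_redrawn"), 0)
})

test_that("Bland-Altman follows its closed form with the n-1 denominator", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  ba1 <- bland_altman(c(2, 3, 4), c(1, 2, 3))   # a - b = +1
  expect_equal(ba1$bias, 1)
  expect_equal(ba1$sd_diff, 0)
  d <- c(0.1, -0.1, 0.3, -0.3)
  ba2 <- bland_altman(d, rep(0, 4))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd_diff, sqrt(sum(d^2) / 3))
  expect_equal(ba2$loa_high, 1.96 * sqrt(sum(d^2) / 3))
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("roc_curve starts at (0,0), ends at (1,1), CI brackets the AUC", {
  with_seed_test(8, {
    s <- rnorm(60) + rep(c(0, 1.5), each = 30)
    l <- rep(c(FALSE, TRUE), each = 30)
    rr <- roc_curve(s, l, n_boot = 200, seed = 2)
    expect_equal(rr$curve$fpr[1], 0)
    expect_equal(rr$curve$tpr[1], 0)
    expect_equal(rr$curve$fpr[nrow(rr$curve)], 1)
    expect_equal(rr$curve$tpr[nrow(rr$curve)], 1)
    expect_lte(rr$ci_low, rr$auc)
    expect_gte(rr$ci_high, rr$auc)
  })
})

test_that("validate_cohort recomposes its component tests exactly", {
  rec <- simulate_records(60, seed = 14)
  v <- validate_cohort(rec, n_boot = 100, seed = 5)
  row <- v$correlations[v$correlations$criterion == "fev1_fvc" &
                          v$correlations$predictor_a == "swes" &
                          v$correlations$predictor_b == "lav950", ]
  direct <- meng_test(rec$swes, rec$lav950, rec$fev1_fvc)
  expect_equal(row$z, direct$z_stat)
  expect_equal(row$p_value, direct$p_value)
  dl_row <- v$roc_comparisons[v$roc_comparisons$endpoint == "obstructed" &
                                v$roc_comparisons$score_a == "swes" &
                                v$roc_comparisons$score_b == "lav950", ]
  direct_dl <- delong_test(rec$swes, rec$lav950, rec$obstructed)
  expect_equal(dl_row$z, direct_dl$z_stat)
  expect_equal(dl_row$p_value, direct_dl$p_value)
})

test_that("deterministic severity-spirometry link yields |r| = 1 in validation", {
  rec <- simulate_records(40, coupling = 0, swes_noise_sd = 0, seed = 9)
  pr <- pearson_r(rec$swes, rec$fev1_fvc)
  expect_equal(abs(pr$r), 1)
})

test_that("tidiers return well-formed tibbles", {
  mt <- meng_test(r_xy = 0.5, r_zy = 0.2, r_xz = 0.4, n = 50)
  expect_s3_class(tidy(mt), "tbl_df")
  expect_named(tidy(mt), c("r_xy", "r_zy", "r_xz", "statistic", "p.value",
                           "n", "alternative"))
  ba <- bland_altman(c(1, 2, 3), c(1.1, 2.2, 2.9))
  expect_equal(nrow(tidy(ba)), 3)
  expect_equal(glance(ba)$n, 3)
})
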