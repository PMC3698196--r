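test_that("tumor volume follows the prolate-ellipsoid formula", {
  expect_equal(tumor_volume(1, 1, 1), pi / 6, tolerance = 1e-12)
  expect_equal(round(tumor_volume(1, 1, 1), 4), 0.5236)
  expect_equal(round(tumor_volume(0.6, 0.5, 0.5), 4), 0.0785)
  expect_error(tumor_volume(0, 1, 1), "positive")
})

test_that("mean gray intensity averages the ROI pixels", {
  img <- matrix(19, 32, 32)
  expect_equal(mean_gray_intensity(img, c(0, 32, 0, 32)), 19)
  img2 <- matrix(0, 32, 32)
  img2[, 17:32] <- 30
  expect_equal(mean_gray_intensity(img2, c(0, 32, 0, 32)), 15)
  expect_error(mean_gray_intensity(img, c(0, 40, 0, 32)), "outside")
  expect_error(mean_gray_intensity(img, c(0, 0, 0, 4)), "empty")
})

test_that("treated frames render brighter than control frames", {
  p <- default_pulse()
  ref <- default_reference(p)
  ctrl <- simulate_tissue_frame(p, tissue_response(-10.66, -57.10), seed = 21)
  trt <- simulate_tissue_frame(p, tissue_response(-5.49, -49.81), seed = 22)
  rect <- c(2, 60, 1100, 192)
  lvl <- qustr:::peak_envelope(ref)
  gi_c <- mean_gray_intensity(ctrl, rect, ref_level = lvl, gain_db = 25)
  gi_t <- mean_gray_intensity(trt, rect, ref_level = lvl, gain_db = 25)
  expect_gt(gi_t, gi_c)
})

test_that("pooled t-test reproduces the hand-computed example", {
  tt <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_lt(abs(tt$t + 3.674), 1e-3)
  expect_lt(abs(tt$p - 0.0213), 5e-4)
  expect_equal(tt$df, 4)
  # symmetry
  rev <- two_sample_ttest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$t, -tt$t)
  expect_equal(rev$p, tt$p)
  # degenerate cases
  same <- two_sample_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_ttest(c(2, 2, 2), c(3, 3, 3)), "degenerate")
  expect_error(two_sample_ttest(1, c(1, 2)), "n >= 2")
})

test_that("assumption checks behave under the null and detect variance ratios", {
  set.seed(7)
  x <- rnorm(50); y <- rnorm(50)
  ac <- assumption_checks(x, y)
  expect_gt(ac$ks_p_x, 0.01)
  expect_gt(ac$levene_p, 0.01)
  ac2 <- assumption_checks(x, 10 * y)
  expect_lt(ac2$levene_p, 0.001)
  const <- assumption_checks(rep(1, 5), rnorm(5))
  expect_true(is.na(const$ks_p_x))
})

test_that("KS p-values are roughly uniform under the null", {
  set.seed(11)
  ps <- replicate(200, assumption_checks(rnorm(30), rnorm(30))$ks_p_x)
  expect_gt(mean(ps), 0.35)
  expect_gt(min(ps), 0)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 10)), "zero-variance")
  expect_error(pearson_correlation(x, 1:9), "equal length")
  set.seed(3)
  rs <- replicate(100, abs(pearson_correlation(rnorm(24), rnorm(24))$r))
  expect_gte(mean(rs < 0.5), 0.95)
})

test_that("LOOCV separates well-separated clusters perfectly", {
  set.seed(5)
  f <- rbind(matrix(rnorm(24, 0, 0.1), 12),
             matrix(rnorm(24, 5, 0.1), 12))
  lab <- rep(c("control", "treated"), each = 12)
  cv <- loocv_classify(f, lab)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
})

test_that("LOOCV metrics satisfy the accuracy decomposition", {
  coh <- simulate_feature_cohort(12, seed = 31)
  cv <- loocv_classify(cbind(coh$slope, coh$midband), coh$group)
  n_pos <- sum(coh$group == "treated")
  n_neg <- sum(coh$group == "control")
  expect_equal(cv$accuracy,
               (cv$sensitivity * n_pos + cv$specificity * n_neg) /
                 (n_pos + n_neg),
               tolerance = 1e-12)
})

test_that("LOOCV predictions match MASS::lda with equal priors", {
  for (s in c(2, 17, 91)) {
    coh <- simulate_feature_cohort(12, seed = s)
    X <- cbind(coh$slope, coh$midband)
    mine <- loocv_classify(X, coh$group)$predictions
    oracle <- MASS::lda(X, grouping = factor(coh$group),
                        prior = c(0.5, 0.5), CV = TRUE)$class
    expect_identical(mine, as.character(oracle))
  }
})

test_that("LOOCV is invariant to a shared positive affine feature map", {
  coh <- simulate_feature_cohort(12, seed = 53)
  X <- cbind(coh$slope, coh$midband)
  a <- loocv_classify(X, coh$group)
  b <- loocv_classify(3.7 * X + 11, coh$group)
  expect_identical(a$predictions, b$predictions)
})

test_that("shuffled labels give chance-level LOOCV accuracy", {
  accs <- sapply(1:150, function(s) {
    coh <- simulate_feature_cohort(12, seed = 60)  # fixed features
    set.seed(7000 + s)
    lab <- sample(coh$group)
    loocv_classify(cbind(coh$slope, coh$midband), lab)$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("singular pooled covariance falls back with a warning", {
  f <- cbind(c(1, 1, 1, 1, 2, 2, 2, 2), c(2, 2, 2, 2, 4, 4, 4, 4))
  lab <- rep(c("control", "treated"), each = 4)
  w <- testthat::capture_warnings(cv <- loocv_classify(f, lab))
  expect_true(any(grepl("singular", w)))
  expect_true(is.finite(cv$accuracy))
})

test_that("cohort report aggregates group statistics and classifications", {
  coh <- simulate_feature_cohort(12, seed = 77)
  set.seed(78)
  records <- data.frame(
    sample_id = sprintf("s%02d", 1:24), group = coh$group,
    length_cm = runif(24, 0.4, 0.8), width_cm = runif(24, 0.4, 0.8),
    depth_cm = runif(24, 0.4, 0.8),
    gray_intensity = c(rnorm(12, 15.4, 3.9), rnorm(12, 19.0, 1.3)),
    slope = coh$slope, midband = coh$midband,
    nuclei_density = c(rnorm(12, 334.5, 44.6), rnorm(12, 78.5, 13.1)))
  rpt <- cohort_report(records)
  expect_s3_class(rpt, "qus_report")
  expect_equal(rpt$measures$volume$control_mean,
               mean(pi / 6 * records$length_cm[1:12] *
                      records$width_cm[1:12] * records$depth_cm[1:12]))
  expect_equal(rpt$measures$slope$percent_change,
               percent_change(mean(coh$slope[1:12]), mean(coh$slope[13:24])))
  expect_lt(rpt$correlations$slope_nuclei$r, 0)  # density falls as SS rises
  expect_false(is.null(rpt$loocv))
  # determinism
  expect_identical(capture.output(print(rpt)),
                   capture.output(print(cohort_report(records))))
  # missing measures are marked absent, not fatal
  records$nuclei_density[3] <- NA
  rpt2 <- cohort_report(records)
  expect_true(rpt2$measures$nuclei_density$absent)
})
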