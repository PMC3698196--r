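#' Prolate-ellipsoid tumor volume
#'
#' The standard calliper formula `volume = pi/6 * length * width * depth`.
#'
#' @param length,width,depth Calliper dimensions, cm; all must be positive.
#' @return Volume in cubic centimetres.
#' @examples
#' tumor_volume(1, 1, 1)  # 0.5236
#' @export
tumor_volume <- function(length, width, depth) {
  if (any(c(length, width, depth) <= 0)) {
    stop_qustr("all three calliper dimensions must be positive")
  }
  pi / 6 * length * width * depth
}

#' Build a B-mode proxy image from an RF frame
#'
#' Envelope detection (magnitude of the analytic signal per line), log
#' compression over `dynamic_range` dB and linear mapping to 8-bit gray
#' levels. `ref_level` fixes the 0 dB point; pass the calibration frame's
#' peak envelope so intensities are comparable across frames (brighter =
#' stronger backscatter). With `ref_level = NULL` the frame's own peak is
#' used.
#'
#' @param frame A `qus_rf_frame`.
#' @param dynamic_range Displayed dynamic range, dB.
#' @param ref_level Envelope amplitude displayed at the top of the range
#'   (before `gain_db`), or `NULL` for the frame's own peak.
#' @param gain_db Display (receive) gain applied after normalization, dB;
#'   used to bring diffuse tissue well above the display floor when
#'   `ref_level` is the much stronger calibration echo.
#' @return Numeric matrix of gray levels in 0-255.
#' @export
bmode_image <- function(frame, dynamic_range = 50, ref_level = NULL,
                        gain_db = 0) {
  stopifnot(inherits(frame, "qus_rf_frame"), dynamic_range > 0)
  env <- t(apply(frame$lines, 1, function(x) Mod(analytic_signal(x))))
  if (is.null(ref_level)) ref_level <- max(env)
  db <- 20 * log10(pmax(env / ref_level, 1e-12)) + gain_db
  pmin(pmax((db + dynamic_range) / dynamic_range, 0), 1) * 255
}

# peak envelope of a frame; used as the shared 0 dB display reference
peak_envelope <- function(frame) {
  max(t(apply(frame$lines, 1, function(x) Mod(analytic_signal(x)))))
}

#' Mean gray-scale intensity over a rectangular ROI
#'
#' For an image matrix, the arithmetic mean of the pixel values inside the
#' rectangle. For an RF frame, a B-mode proxy is built first (see
#' [bmode_image()]); this is the echogenicity measurement made on B-mode
#' screenshots in image-editing software.
#'
#' @param x Numeric matrix (gray image) or `qus_rf_frame`.
#' @param rect Rectangle `c(row_start, row_count, col_start, col_count)`,
#'   0-based, half-open, in image pixels (for frames: rows = lines,
#'   cols = samples).
#' @param ... Passed to [bmode_image()] for RF input.
#' @return Mean intensity in 8-bit units.
#' @export
mean_gray_intensity <- function(x, rect, ...) {
  img <- if (inherits(x, "qus_rf_frame")) bmode_image(x, ...) else x
  stopifnot(is.matrix(img), length(rect) == 4L)
  r0 <- rect[1]; nr <- rect[2]; c0 <- rect[3]; ncnt <- rect[4]
  if (nr < 1 || ncnt < 1) stop_qustr("ROI rectangle is empty")
  if (r0 < 0 || c0 < 0 || r0 + nr > nrow(img) || c0 + ncnt > ncol(img)) {
    stop_qustr("ROI rectangle outside the image (%d x %d)",
               nrow(img), ncol(img))
  }
  mean(img[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + ncnt)])
}

#' Pooled-variance two-sample Student's t-test
#'
#' Two-sided, equal-variance Student's t with `n1 + n2 - 2` degrees of
#' freedom (a Welch option is available for unequal variances). Degenerate
#' samples with zero pooled variance return `t = 0, p = 1` when the means
#' agree and raise an error otherwise.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param var_equal Pooled (Student, default) or Welch.
#' @return List with `t`, `p` and `df`.
#' @export
two_sample_ttest <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_qustr("both samples need n >= 2")
  }
  if (var(x) + var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p = 1, df = length(x) + length(y) - 2))
    }
    stop_qustr("degenerate samples: zero variance with unequal means")
  }
  ht <- t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Normality and variance-homogeneity checks
#'
#' One-sample Kolmogorov-Smirnov test of each sample against a normal
#' distribution with the sample's own mean and SD (parameters estimated, as
#' common statistics packages do, which makes the p-value conservative),
#' and Levene's test (centered at the mean) for homogeneity of variance
#' across the two groups.
#'
#' @param x,y Numeric samples, each of length >= 3.
#' @return List with `ks_p_x`, `ks_p_y` (NA for constant samples) and
#'   `levene_p`.
#' @export
assumption_checks <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L) {
    stop_qustr("both samples need n >= 3")
  }
  ks1 <- function(v) {
    if (sd(v) == 0) return(NA_real_)
    suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v))$p.value)
  }
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  lev <- car::leveneTest(c(x, y) ~ g, center = mean)
  list(ks_p_x = ks1(x), ks_p_y = ks1(y),
       levene_p = lev[1, "Pr(>F)"])
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Equal-length numeric samples (n >= 3) with nonzero variance.
#' @return List with `r` and `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_qustr("samples must have equal length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_qustr("correlation undefined for zero-variance samples")
  }
  ht <- cor.test(x, y)
  list(r = unname(ht$estimate), p = ht$p.value)
}

# two-class linear discriminant (pooled covariance, equal priors) trained
# on (features, labels); returns the linear score function w'x + b whose
# positive values predict the positive class
lda_rule <- function(features, positive_mask) {
  m1 <- colMeans(features[positive_mask, , drop = FALSE])
  m0 <- colMeans(features[!positive_mask, , drop = FALSE])
  n1 <- sum(positive_mask); n0 <- sum(!positive_mask)
  p <- ncol(features)
  zero <- matrix(0, p, p)
  s1 <- if (n1 > 1) stats::cov(features[positive_mask, , drop = FALSE]) else zero
  s0 <- if (n0 > 1) stats::cov(features[!positive_mask, , drop = FALSE]) else zero
  sp <- ((n1 - 1) * s1 + (n0 - 1) * s0) / (n1 + n0 - 2)
  w <- tryCatch(solve(sp, m1 - m0), error = function(e) {
    warn_qustr("singular pooled covariance; falling back to diagonal")
    dg <- pmax(diag(sp), .Machine$double.eps)
    (m1 - m0) / dg
  })
  b <- -sum(w * (m1 + m0) / 2)
  list(w = w, b = b)
}

#' Leave-one-out cross-validated linear-discriminant classification
#'
#' For each sample, a two-class linear discriminant (pooled covariance,
#' equal priors) is trained on the remaining samples and the held-out
#' sample is predicted; accuracy, sensitivity and specificity are computed
#' from the held-out predictions. `treated` is the positive class; ties
#' break toward `control`.
#'
#' @param features Numeric matrix (n samples x p features, e.g. spectral
#'   slope and midband fit) or vector for a single feature.
#' @param labels Character/factor labels, `"control"` or `"treated"`.
#' @param positive Positive-class label.
#' @return List with `accuracy`, `sensitivity`, `specificity`,
#'   `predictions` (character vector) and `confusion` (2 x 2 table).
#' @export
loocv_classify <- function(features, labels, positive = "treated") {
  if (is.null(dim(features))) features <- cbind(features)
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  if (n != length(labels)) stop_qustr("features and labels disagree on n")
  pos_mask <- labels == positive
  if (n < 4L || !any(pos_mask) || all(pos_mask)) {
    stop_qustr("need n >= 4 with both classes present")
  }
  neg_label <- setdiff(unique(labels), positive)[1]
  preds <- character(n)
  for (i in seq_len(n)) {
    rule <- lda_rule(features[-i, , drop = FALSE], pos_mask[-i])
    score <- sum(rule$w * features[i, ]) + rule$b
    preds[i] <- if (score > 0) positive else neg_label
  }
  tp <- sum(preds == positive & pos_mask)
  tn <- sum(preds != positive & !pos_mask)
  list(accuracy = (tp + tn) / n,
       sensitivity = tp / sum(pos_mask),
       specificity = tn / sum(!pos_mask),
       predictions = preds,
       confusion = table(truth = labels, predicted = preds))
}

#' Draw a feature-level cohort from group normal distributions
#'
#' Samples per-tumor spectral slope and midband fit directly from the two
#' groups' normal distributions (features independent within group), the
#' distributional layer of the full simulator. Used for fast replication of
#' the classifier metrics.
#'
#' @param n_per_group Tumors per group.
#' @param group_params List with `control` and `treated`, each
#'   `list(ss = c(mean, sd), mbf = c(mean, sd))`.
#' @param seed Integer seed.
#' @return Data frame with `group`, `slope`, `midband`.
#' @export
simulate_feature_cohort <- function(n_per_group = 12,
                                    group_params = printed_group_params(),
                                    seed = 1L) {
  stopifnot(n_per_group >= 2)
  with_local_seed(seed, {
    draw <- function(g, label) {
      data.frame(group = label,
                 slope = rnorm(n_per_group, g$ss[1], g$ss[2]),
                 midband = rnorm(n_per_group, g$mbf[1], g$mbf[2]))
    }
    rbind(draw(group_params$control, "control"),
          draw(group_params$treated, "treated"))
  })
}

#' Published group parameters of the chemotherapy-response study
#'
#' Mean and SD of the spectral slope (dB/MHz), midband fit (dB), nuclei
#' density (counts/HPF) and tumor volume (cm^3) for saline-control and
#' adriamycin-treated MCF-7 xenografts after 7 days of treatment, as
#' reported for 12 animals per group.
#'
#' @return Nested list with `control` and `treated` entries (`ss`, `mbf`,
#'   `nuclei`, `volume`, each `c(mean, sd)`).
#' @export
printed_group_params <- function() {
  list(
    control = list(ss = c(-10.66, 2.96), mbf = c(-57.10, 7.68),
                   nuclei = c(334.50, 44.57), volume = c(0.17, 0.08)),
    treated = list(ss = c(-5.49, 2.69), mbf = c(-49.81, 5.40),
                   nuclei = c(78.51, 13.11), volume = c(0.08, 0.03)))
}

#' Replicate the LOOCV classification over simulated cohorts
#'
#' Draws `n_replicates` independent cohorts of `n_per_group` tumors per
#' group from the group normal distributions and runs the two-feature
#' LOOCV linear discriminant on each, averaging accuracy, sensitivity and
#' specificity across replicates.
#'
#' @param n_replicates Number of simulated cohorts.
#' @param n_per_group Tumors per group per cohort.
#' @param group_params As in [simulate_feature_cohort()].
#' @param seed Master seed; replicate r uses a seed derived from it.
#' @return List with `accuracy`, `sensitivity`, `specificity` (means over
#'   replicates), their SDs (`*_sd`), and `n_replicates`.
#' @export
loocv_replication <- function(n_replicates = 1000, n_per_group = 12,
                              group_params = printed_group_params(),
                              seed = 1L) {
  stopifnot(n_replicates >= 2)
  res <- vapply(seq_len(n_replicates), function(r) {
    coh <- simulate_feature_cohort(n_per_group, group_params,
                                   seed = derive_seed(seed, r))
    cv <- loocv_classify(cbind(coh$slope, coh$midband), coh$group)
    c(cv$accuracy, cv$sensitivity, cv$specificity)
  }, numeric(3))
  list(accuracy = mean(res[1, ]), sensitivity = mean(res[2, ]),
       specificity = mean(res[3, ]),
       accuracy_sd = sd(res[1, ]), sensitivity_sd = sd(res[2, ]),
       specificity_sd = sd(res[3, ]),
       n_replicates = n_replicates)
}
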