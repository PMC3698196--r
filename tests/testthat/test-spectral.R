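test_that("gate_roi extracts the stated sample window", {
  lines <- matrix(seq_len(64 * 2048), nrow = 64)
  fr <- rf_frame(lines, sampling_rate = 35)
  segs <- gate_roi(fr, roi_spec(12, 4.224, first_line = 10, n_lines = 8))
  expect_equal(nrow(segs), 8L)
  expect_equal(ncol(segs), round(2 * 4.224 / 1.54 * 35))
  # depth_start maps to floor(2 d / c * fs), 0-based half-open
  start <- floor(2 * 12 / 1.54 * 35)
  expect_equal(segs[1, 1], fr$lines[11, start + 1])
})

test_that("out-of-bounds ROIs are rejected with the offending bound", {
  fr <- rf_frame(matrix(0, 4, 256), sampling_rate = 35)
  expect_error(gate_roi(fr, roi_spec(5, 4, 0, 4)), "depth range")
  expect_error(gate_roi(fr, roi_spec(0.5, 2, 3, 4)), "line range")
  expect_warning(gate_roi(fr, roi_spec(0.5, 1, 0, 2), center_frequency = 6),
                 "10 pulse periods")
})

test_that("windowed power spectrum of an all-ones segment equals the Hamming window spectrum", {
  L <- 128L
  ps <- windowed_power_spectrum(rep(1, L), sampling_rate = 35)
  # independent oracle: direct O(L^2) DFT of the Hamming formula
  n <- 0:(L - 1)
  wh <- 0.54 - 0.46 * cos(2 * pi * n / (L - 1))
  direct <- vapply(seq_len(L %/% 2), function(k) {
    sum(wh * cos(2 * pi * k * n / L))^2 + sum(wh * sin(2 * pi * k * n / L))^2
  }, numeric(1))
  # the Nyquist bin of the symmetric window is an exact zero (floored by the
  # implementation, ~1e-27 in the direct sum); compare the rest
  keep <- seq_len(L %/% 2 - 1L)
  expect_equal(ps$magnitude_db[keep], 10 * log10(direct[keep]),
               tolerance = 1e-8)
})

test_that("a pure sinusoid at bin k peaks at bin k", {
  L <- 256L
  k <- 40L
  x <- sin(2 * pi * k * (0:(L - 1)) / L)
  ps <- windowed_power_spectrum(x, sampling_rate = 35)
  expect_equal(which.max(ps$magnitude_db), k)
  expect_equal(ps$frequencies[k], k * 35 / L)
})

test_that("averaging identical segments reproduces the single-segment spectrum", {
  x <- rnorm(128)
  one <- windowed_power_spectrum(x, 35)
  two <- windowed_power_spectrum(rbind(x, x), 35)
  expect_equal(two$magnitude_db, one$magnitude_db, tolerance = 1e-12)
  expect_equal(two$n_lines_averaged, 2L)
})

test_that("all-zero segments are floored with a warning", {
  expect_warning(ps <- windowed_power_spectrum(numeric(128), 35), "floored")
  expect_true(all(ps$magnitude_db == -300))
})

test_that("calibration is subtraction in dB", {
  x <- rnorm(192)
  a <- windowed_power_spectrum(x, 35)
  expect_error(calibrate(a, windowed_power_spectrum(rnorm(128), 35)),
               "different frequency grids")
  cal <- calibrate(a, a, band = c(4, 8))
  expect_true(all(abs(cal$magnitude_db) < 1e-12))
  # amplitude x2 on the reference drops the calibrated level by 6.02 dB
  b <- windowed_power_spectrum(2 * x, 35)
  cal2 <- calibrate(a, b, band = c(4, 8))
  expect_equal(cal2$magnitude_db,
               rep(-20 * log10(2), length(cal2$magnitude_db)),
               tolerance = 1e-9)
})

test_that("analysis band at 6.02 dB recovers the -6 dB bandwidth of a Gaussian spectrum", {
  f <- seq(0.25, 17.5, by = 0.25)
  mag <- -6.02 * ((f - 6) / 1.5)^2   # Gaussian pulse spectrum in dB
  ref <- structure(list(frequencies = f, magnitude_db = mag,
                        n_lines_averaged = 1L),
                   class = "qus_power_spectrum")
  band <- analysis_band(ref, 6.02)
  expect_lt(abs((band[2] - band[1]) - 3), 0.25 + 1e-9)
  expect_error(analysis_band(ref, 0), "degenerate")
  mono <- structure(list(frequencies = f, magnitude_db = f,
                         n_lines_averaged = 1L),
                    class = "qus_power_spectrum")
  expect_error(analysis_band(mono), "interior peak")
})

test_that("regression on an exact line returns its parameters", {
  f <- seq(0.5, 17.5, by = 0.5)
  line <- structure(list(frequencies = f, magnitude_db = 3 * f - 30,
                         band = c(4, 8)),
                    class = "qus_calibrated_spectrum")
  fit <- fit_spectral_params(line)
  expect_equal(fit$slope, 3, tolerance = 1e-9)
  expect_equal(fit$midband, 3 * 6 - 30, tolerance = 1e-9)
  expect_equal(fit$intercept, -30, tolerance = 1e-9)
  expect_equal(fit$center_frequency, 6)
  # SpectralParams invariant
  expect_equal(fit$midband, fit$slope * fit$center_frequency + fit$intercept,
               tolerance = 1e-9)

  flat <- structure(list(frequencies = f,
                         magnitude_db = rep(-20, length(f)),
                         band = c(4, 8)),
                    class = "qus_calibrated_spectrum")
  ff <- fit_spectral_params(flat)
  expect_equal(ff$slope, 0, tolerance = 1e-12)
  expect_equal(ff$midband, -20, tolerance = 1e-12)

  narrow <- structure(list(frequencies = f, magnitude_db = 3 * f - 30,
                           band = c(4, 4.6)),
                      class = "qus_calibrated_spectrum")
  expect_error(fit_spectral_params(narrow), "fewer than 3")
})

test_that("a symmetric zigzag perturbation leaves the OLS slope unbiased", {
  f <- seq(4, 8, by = 0.25)
  zig <- rep(c(1, -1), length.out = length(f))
  zig <- zig - mean(zig)
  spec <- structure(list(frequencies = f,
                         magnitude_db = 3 * f - 30 + zig,
                         band = c(4, 8)),
                    class = "qus_calibrated_spectrum")
  fit <- fit_spectral_params(spec)
  # oracle: closed-form OLS on the constructed grid
  slope_oracle <- sum((f - mean(f)) * (3 * f - 30 + zig)) /
    sum((f - mean(f))^2)
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-12)
  expect_lt(abs(fit$slope - 3), 0.2)
})

test_that("exact-line property holds for random slopes, intercepts and bands", {
  f <- seq(0.25, 17, by = 0.25)
  set.seed(42)
  for (i in 1:25) {
    a <- runif(1, -20, 20); b <- runif(1, -80, 20)
    lo <- runif(1, 1, 10); hi <- lo + runif(1, 1.5, 6)
    spec <- structure(list(frequencies = f, magnitude_db = a * f + b,
                           band = c(lo, hi)),
                      class = "qus_calibrated_spectrum")
    fit <- fit_spectral_params(spec)
    fc <- (lo + hi) / 2
    expect_equal(fit$slope, a, tolerance = 1e-9)
    expect_equal(fit$midband, a * fc + b, tolerance = 1e-9)
  }
})

test_that("three identical ROIs average to the single-ROI result", {
  p <- default_pulse()
  ref <- default_reference(p)
  fr <- simulate_tissue_frame(p, tissue_response(-8, -50), seed = 2)
  span <- 192 * 1.54 / 70
  roi <- roi_spec(15 - span / 2, span, 2, 20)
  same <- tumor_spectral_params(fr, ref, list(roi, roi, roi))
  single <- fit_spectral_params(calibrate(
    windowed_power_spectrum(gate_roi(fr, roi), 35),
    qustr:::reference_spectrum(ref, 192L)))
  expect_equal(same$slope, single$slope, tolerance = 1e-12)
  expect_equal(same$midband, single$midband, tolerance = 1e-12)
  # tumor-level values are the arithmetic means of the per-ROI fits
  mixed <- tumor_spectral_params(fr, ref, default_rois())
  expect_equal(mixed$slope, mean(mixed$per_roi$slope), tolerance = 1e-12)
  expect_equal(mixed$midband, mean(mixed$per_roi$midband), tolerance = 1e-12)
})

test_that("ROIs with different gate lengths are rejected", {
  p <- default_pulse()
  ref <- default_reference(p)
  fr <- simulate_tissue_frame(p, tissue_response(-8, -50), seed = 2)
  rois <- default_rois()
  rois[[3]] <- roi_spec(13, 2, 42, 20)
  expect_error(tumor_spectral_params(fr, ref, rois), "common gate length")
  expect_error(tumor_spectral_params(fr, ref, rois[1:2]), "exactly 3")
})

test_that("percent change matches the published worked examples", {
  expect_equal(round(percent_change(-10.66, -5.49), 1), 48.5)
  expect_equal(round(percent_change(-57.10, -49.81), 1), 12.8)
  expect_equal(percent_change(3, 3), 0)
  expect_error(percent_change(0, 1), "nonzero")
})
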