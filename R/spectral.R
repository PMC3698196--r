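#' Rectangular region-of-interest specification
#'
#' ROIs are defined in physical depth (two-way travel at the frame's sound
#' speed) and in line indices. Sample and line indices are 0-based; gates
#' are half-open `[start, stop)`. `depth_start` maps to sample
#' `floor(2 * depth_start / c * fs)` and the gate length is
#' `round(2 * depth_span / c * fs)` samples.
#'
#' @param depth_start Top of the ROI, mm.
#' @param depth_span Axial extent of the ROI, mm.
#' @param first_line First scan line (0-based).
#' @param n_lines Number of lines in the ROI.
#' @return An object of class `qus_roi`.
#' @export
roi_spec <- function(depth_start, depth_span, first_line, n_lines) {
  stopifnot(depth_start >= 0, n_lines >= 1, first_line >= 0)
  if (depth_span <= 0) stop_qustr("depth_span must be positive")
  structure(list(depth_start = depth_start, depth_span = depth_span,
                 first_line = as.integer(first_line),
                 n_lines = as.integer(n_lines)),
            class = "qus_roi")
}

#' Extract the gated echo segments of an ROI
#'
#' @param frame A `qus_rf_frame`.
#' @param roi A [roi_spec()].
#' @param center_frequency Optional pulse center frequency (MHz); when given,
#'   a warning is issued if the gate is shorter than 10 pulse periods.
#' @return A numeric matrix, one row per line, one column per gated sample.
#' @export
gate_roi <- function(frame, roi, center_frequency = NULL) {
  stopifnot(inherits(frame, "qus_rf_frame"), inherits(roi, "qus_roi"))
  fs <- frame$sampling_rate
  cs <- frame$sound_speed
  start <- depth_to_sample(roi$depth_start, fs, cs)     # 0-based
  len <- round(2 * roi$depth_span / cs * fs)
  stop <- start + len                                   # half-open
  n_samples <- ncol(frame$lines)
  n_lines <- nrow(frame$lines)
  if (start < 0 || stop > n_samples) {
    stop_qustr("ROI samples [%d, %d) outside frame depth range [0, %d)",
               start, stop, n_samples)
  }
  if (roi$first_line < 0 || roi$first_line + roi$n_lines > n_lines) {
    stop_qustr("ROI lines [%d, %d) outside frame line range [0, %d)",
               roi$first_line, roi$first_line + roi$n_lines, n_lines)
  }
  if (!is.null(center_frequency) && len < 10 * fs / center_frequency) {
    warn_qustr("gate of %d samples is shorter than 10 pulse periods", len)
  }
  frame$lines[(roi$first_line + 1L):(roi$first_line + roi$n_lines),
              (start + 1L):stop, drop = FALSE]
}

#' Hamming-windowed averaged power spectrum
#'
#' Each gated segment is multiplied by the L-point Hamming window (to
#' suppress spectral side lobes), Fourier transformed, and the squared
#' magnitudes are averaged across scan lines in linear power before
#' conversion to dB. Only positive-frequency bins are returned; no
#' zero-padding is applied.
#'
#' @param segments Numeric matrix of gated segments (rows = lines), or a
#'   single numeric vector; all segments must share length `L >= 64`.
#' @param sampling_rate Sampling rate, MHz.
#' @param floor_db Guard floor applied (with a warning) where the averaged
#'   power is zero.
#' @return An object of class `qus_power_spectrum`: list with `frequencies`
#'   (MHz, `k * fs / L` for `k = 1 .. floor(L/2)`), `magnitude_db`, and
#'   `n_lines_averaged`.
#' @export
windowed_power_spectrum <- function(segments, sampling_rate,
                                    floor_db = -300) {
  if (is.numeric(segments) && is.null(dim(segments))) {
    segments <- matrix(segments, nrow = 1L)
  }
  stopifnot(is.matrix(segments), nrow(segments) >= 1L)
  L <- ncol(segments)
  if (L < 64L) stop_qustr("segments must have length >= 64, got %d", L)
  w <- as.numeric(signal::hamming(L))
  spec <- stats::mvfft(t(segments * rep(w, each = nrow(segments))))
  pw <- rowMeans(Mod(spec)^2)
  k <- seq_len(L %/% 2)
  pw <- pw[k + 1L]                       # positive frequencies, drop DC
  if (any(rowSums(abs(segments)) == 0)) {
    warn_qustr("all-zero segment(s): power floored at %g dB", floor_db)
  }
  mag <- rep(floor_db, length(pw))
  zero <- pw <= 0
  mag[!zero] <- pmax(db_pow(pw[!zero]), floor_db)
  structure(list(frequencies = k * sampling_rate / L,
                 magnitude_db = mag,
                 n_lines_averaged = nrow(segments)),
            class = "qus_power_spectrum")
}

#' Analysis band from the reference spectrum
#'
#' Returns the contiguous frequency interval around the reference-spectrum
#' peak over which the magnitude stays within `threshold_db` of the peak.
#' The regression of the calibrated spectrum is confined to this band, where
#' the system has usable sensitivity.
#'
#' @param reference A `qus_power_spectrum` of the calibration echo. The peak
#'   must be interior to the frequency grid.
#' @param threshold_db Drop from the peak (dB) delimiting the band.
#' @return Numeric `c(f_lo, f_hi)` in MHz.
#' @export
analysis_band <- function(reference, threshold_db = 6) {
  stopifnot(inherits(reference, "qus_power_spectrum"), threshold_db >= 0)
  mag <- reference$magnitude_db
  f <- reference$frequencies
  pk <- which.max(mag)
  if (pk == 1L || pk == length(mag)) {
    stop_qustr("reference spectrum has no interior peak")
  }
  keep <- mag >= mag[pk] - threshold_db
  lo <- pk
  while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- pk
  while (hi < length(mag) && keep[hi + 1L]) hi <- hi + 1L
  if (hi - lo < 1L) {
    stop_qustr("analysis band is degenerate (single bin) at threshold %g dB",
               threshold_db)
  }
  c(f[lo], f[hi])
}

#' Calibrate a tissue spectrum against the reference
#'
#' Division by the calibration-target spectrum becomes subtraction in dB;
#' the result is the system-independent backscatter transfer function of the
#' tissue.
#'
#' @param tissue,reference `qus_power_spectrum` objects on identical
#'   frequency grids.
#' @param band Optional `c(f_lo, f_hi)` regression band; defaults to
#'   [analysis_band()] of the reference at `threshold_db`.
#' @param threshold_db Band threshold used when `band` is `NULL`.
#' @return An object of class `qus_calibrated_spectrum`: list with
#'   `frequencies`, `magnitude_db` (dB relative to the reference) and `band`.
#' @export
calibrate <- function(tissue, reference, band = NULL, threshold_db = 6) {
  stopifnot(inherits(tissue, "qus_power_spectrum"),
            inherits(reference, "qus_power_spectrum"))
  if (length(tissue$frequencies) != length(reference$frequencies) ||
      any(abs(tissue$frequencies - reference$frequencies) > 1e-9)) {
    stop_qustr("tissue and reference spectra are on different frequency grids")
  }
  if (is.null(band)) band <- analysis_band(reference, threshold_db)
  f <- tissue$frequencies
  if (band[1] >= band[2] || band[1] < f[1] || band[2] > f[length(f)]) {
    stop_qustr("band [%g, %g] MHz is not inside the frequency grid",
               band[1], band[2])
  }
  structure(list(frequencies = f,
                 magnitude_db = tissue$magnitude_db - reference$magnitude_db,
                 band = band),
            class = "qus_calibrated_spectrum")
}

#' Spectral slope, midband fit and intercept by linear regression
#'
#' Ordinary least squares of the calibrated magnitude (dB) on frequency
#' (MHz) over the analysis band. The spectral slope (SS) is the regression
#' slope; the midband fit (MBF) is the value of the fit at the band center;
#' the intercept is the fit extrapolated to 0 MHz.
#'
#' @param spectrum A `qus_calibrated_spectrum`.
#' @return An object of class `qus_spectral_params`: list with `slope`
#'   (dB/MHz), `midband` (dB), `intercept` (dB), `center_frequency` (MHz)
#'   and `band`.
#' @export
fit_spectral_params <- function(spectrum) {
  stopifnot(inherits(spectrum, "qus_calibrated_spectrum"))
  band <- spectrum$band
  sel <- spectrum$frequencies >= band[1] - 1e-12 &
    spectrum$frequencies <= band[2] + 1e-12
  if (sum(sel) < 3L) {
    stop_qustr("fewer than 3 frequency bins inside band [%g, %g] MHz",
               band[1], band[2])
  }
  f <- spectrum$frequencies[sel]
  m <- spectrum$magnitude_db[sel]
  cf <- coef(lm(m ~ f))
  fc <- (band[1] + band[2]) / 2
  structure(list(slope = unname(cf[2]),
                 midband = unname(cf[2] * fc + cf[1]),
                 intercept = unname(cf[1]),
                 center_frequency = fc,
                 band = band),
            class = "qus_spectral_params")
}

#' @export
print.qus_spectral_params <- function(x, ...) {
  cat(sprintf(
    "Spectral parameters over %.2f-%.2f MHz: SS = %.3f dB/MHz, MBF = %.3f dB\n",
    x$band[1], x$band[2], x$slope, x$midband))
  invisible(x)
}

# Power spectrum of the reference echo using a gate of `len` samples
# centered on the echo envelope peak, so the calibration sees the full
# specular reflection under the same window as the tissue gate.
reference_spectrum <- function(reference, len) {
  line <- reference$lines[1L, ]
  n <- length(line)
  peak <- which.max(Mod(analytic_signal(line)))
  start <- peak - len %/% 2
  start <- min(max(start, 1L), n - len + 1L)
  seg <- reference$lines[, start:(start + len - 1L), drop = FALSE]
  windowed_power_spectrum(seg[1L, , drop = FALSE], reference$sampling_rate)
}

#' Tumor-level spectral parameters from three ROIs
#'
#' Computes per-ROI calibrated spectra and regression parameters with a
#' shared analysis band derived from the reference echo, then averages the
#' slope and midband fit across the ROIs for the final tumor-level value.
#' The reference echo is gated with the same gate length as the tissue ROIs,
#' centered on its envelope peak.
#'
#' @param frame Tissue `qus_rf_frame`.
#' @param reference Reference `qus_rf_frame` (quartz-flat echo).
#' @param rois List of three [roi_spec()] with identical `depth_span`.
#' @param threshold_db Analysis-band threshold below the reference peak, dB.
#' @return A `qus_spectral_params` whose `slope`/`midband`/`intercept` are
#'   ROI averages; per-ROI values are attached as `per_roi` (data frame).
#' @export
tumor_spectral_params <- function(frame, reference, rois, threshold_db = 6) {
  stopifnot(inherits(frame, "qus_rf_frame"),
            inherits(reference, "qus_rf_frame"))
  if (!is.list(rois) || length(rois) != 3L ||
      !all(vapply(rois, inherits, logical(1), "qus_roi"))) {
    stop_qustr("rois must be a list of exactly 3 roi_spec objects")
  }
  lens <- vapply(rois, function(r) {
    round(2 * r$depth_span / frame$sound_speed * frame$sampling_rate)
  }, numeric(1))
  if (length(unique(lens)) != 1L) {
    stop_qustr("the three ROIs must share a common gate length, got %s",
               paste(lens, collapse = ", "))
  }
  ref_spec <- reference_spectrum(reference, as.integer(lens[1]))
  band <- analysis_band(ref_spec, threshold_db)
  fits <- lapply(rois, function(r) {
    seg <- gate_roi(frame, r)
    fit_spectral_params(calibrate(windowed_power_spectrum(
      seg, frame$sampling_rate), ref_spec, band = band))
  })
  fc <- (band[1] + band[2]) / 2
  slope <- mean(vapply(fits, `[[`, numeric(1), "slope"))
  midband <- mean(vapply(fits, `[[`, numeric(1), "midband"))
  out <- structure(list(slope = slope, midband = midband,
                        intercept = midband - slope * fc,
                        center_frequency = fc, band = band),
                   class = "qus_spectral_params")
  out$per_roi <- data.frame(
    roi = seq_along(fits),
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    midband = vapply(fits, `[[`, numeric(1), "midband"))
  out
}

#' Percent change of a group mean
#'
#' `100 * (treated_mean - control_mean) / abs(control_mean)`: the convention
#' under which a slope moving from -10.66 to -5.49 dB/MHz is a 48.5%
#' increase.
#'
#' @param control_mean,treated_mean Group means; `control_mean` must be
#'   nonzero.
#' @return Percent change (positive = increase).
#' @export
percent_change <- function(control_mean, treated_mean) {
  if (!is.finite(control_mean) || control_mean == 0) {
    stop_qustr("control mean must be nonzero to express a percent change")
  }
  100 * (treated_mean - control_mean) / abs(control_mean)
}
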