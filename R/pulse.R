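#' Construct a Gaussian-enveloped ultrasound pulse
#'
#' Builds the transmit/receive pulse used by the RF simulator: a sinusoid at
#' `center_frequency` under a Gaussian envelope whose width is chosen so the
#' -6 dB spectral width equals `fractional_bandwidth * center_frequency`.
#' This emulates a clinical linear-array transducer (default 6 MHz sampled at
#' 35 MHz).
#'
#' @param center_frequency Center frequency in MHz; must lie below Nyquist
#'   (`sampling_rate / 2`).
#' @param fractional_bandwidth -6 dB fractional bandwidth (0 < fbw < 1).
#' @param sampling_rate Sampling rate in MHz.
#' @param duration Pulse duration in microseconds; must cover at least three
#'   envelope standard deviations on each side of the pulse center.
#' @return An object of class `qus_pulse`: a list with fields
#'   `center_frequency`, `fractional_bandwidth`, `sampling_rate` (MHz),
#'   `duration` (us), `sigma_t` (envelope SD, us) and `samples` (numeric
#'   vector, peak amplitude 1 at the pulse center).
#' @examples
#' p <- make_pulse(6, 0.5, 35, 2)
#' length(p$samples)
#' @export
make_pulse <- function(center_frequency = 6, fractional_bandwidth = 0.5,
                       sampling_rate = 35, duration = 2) {
  stopifnot(center_frequency > 0, sampling_rate > 0, duration > 0)
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 1) {
    stop_qustr("fractional_bandwidth must lie in (0, 1), got %g",
               fractional_bandwidth)
  }
  if (center_frequency >= sampling_rate / 2) {
    stop_qustr(
      "center frequency %g MHz is at or above Nyquist (%g MHz)",
      center_frequency, sampling_rate / 2)
  }
  # -6 dB on the amplitude spectrum: exp(-df^2 / (2 sigma_f^2)) = 10^(-6/20)
  # => full width 2 * sigma_f * sqrt(2 * ln(10^0.3)).
  sigma_f <- fractional_bandwidth * center_frequency /
    (2 * sqrt(2 * log(10^(6 / 20))))
  sigma_t <- 1 / (2 * pi * sigma_f)
  if (duration < 6 * sigma_t) {
    stop_qustr(
      "duration %g us does not cover 3 envelope SDs each side (need >= %.3g us)",
      duration, 6 * sigma_t)
  }
  n <- round(duration * sampling_rate)
  if (n %% 2 == 0) n <- n + 1L   # odd length: center sample exactly at t = 0
  t <- (seq_len(n) - (n + 1) / 2) / sampling_rate
  samples <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * center_frequency * t)
  structure(
    list(center_frequency = center_frequency,
         fractional_bandwidth = fractional_bandwidth,
         sampling_rate = sampling_rate,
         duration = duration,
         sigma_t = sigma_t,
         samples = samples),
    class = "qus_pulse")
}

#' @export
print.qus_pulse <- function(x, ...) {
  cat(sprintf(
    "Gaussian pulse: %g MHz, %.0f%% fractional bandwidth, fs = %g MHz, %d samples\n",
    x$center_frequency, 100 * x$fractional_bandwidth, x$sampling_rate,
    length(x$samples)))
  invisible(x)
}

# Continuous-frequency amplitude spectrum of the pulse (DTFT magnitude) at
# frequencies f (MHz); used for exact normalization of the tissue simulator.
pulse_dtft <- function(pulse, f) {
  n <- length(pulse$samples)
  idx <- seq_len(n) - 1
  vapply(f, function(fi) {
    abs(sum(pulse$samples * exp(-2i * pi * fi * idx / pulse$sampling_rate)))
  }, numeric(1))
}
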