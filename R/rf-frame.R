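#' RF echo frames
#'
#' An RF frame is a raster of echo lines: a numeric matrix with one row per
#' scan line and one column per time sample, together with its sampling
#' metadata. Amplitudes are stored in physical units but carry 16-bit
#' semantics: each frame records the `gain` (integer counts per amplitude
#' unit) under which its samples were quantized to signed 16-bit integers,
#' as acquisition systems do, and [write_rf()] stores the integer counts.
#'
#' @param lines Numeric matrix, `n_lines x n_samples` (`n_samples >= 64`).
#' @param sampling_rate Sampling rate in MHz.
#' @param line_pitch Lateral distance between adjacent lines, mm.
#' @param sound_speed Speed of sound, mm/us (soft-tissue convention 1.54).
#' @param kind `"tissue"` or `"reference"`.
#' @param gain Counts per amplitude unit used for 16-bit quantization; when
#'   `NULL` a gain placing the frame peak near 30000 counts is chosen.
#' @return An object of class `qus_rf_frame`.
#' @seealso [simulate_tissue_frame()], [simulate_reference_echo()]
#' @export
rf_frame <- function(lines, sampling_rate, line_pitch = 0.3,
                     sound_speed = QUS_SOUND_SPEED,
                     kind = c("tissue", "reference"), gain = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(lines), is.numeric(lines), sampling_rate > 0,
            line_pitch > 0, sound_speed > 0)
  if (nrow(lines) < 1L) stop_qustr("frame needs at least one line")
  if (ncol(lines) < 64L) {
    stop_qustr("frame needs >= 64 samples per line, got %d", ncol(lines))
  }
  peak <- max(abs(lines))
  if (is.null(gain)) {
    gain <- if (peak > 0) 30000 / peak else 1
  }
  if (peak * gain > 32767) {
    stop_qustr("amplitudes not representable in int16 at gain %g", gain)
  }
  # Emulate 16-bit acquisition: round to integer counts, keep physical units.
  lines <- round(lines * gain) / gain
  structure(
    list(lines = lines, sampling_rate = sampling_rate,
         line_pitch = line_pitch, sound_speed = sound_speed,
         kind = kind, gain = gain),
    class = "qus_rf_frame")
}

#' @export
print.qus_rf_frame <- function(x, ...) {
  cat(sprintf("RF %s frame: %d lines x %d samples, fs = %g MHz, c = %g mm/us\n",
              x$kind, nrow(x$lines), ncol(x$lines), x$sampling_rate,
              x$sound_speed))
  invisible(x)
}

# Depth (mm) to 0-based sample index, two-way travel.
depth_to_sample <- function(depth_mm, sampling_rate, sound_speed) {
  floor(2 * depth_mm / sound_speed * sampling_rate)
}

#' Read and write RF frames
#'
#' Frames are stored in a small self-describing binary container: the magic
#' string `QUSRF1\n`, one line of JSON metadata (`n_lines`, `n_samples`,
#' `sampling_rate_mhz`, `line_pitch_mm`, `sound_speed_mm_us`, `kind`,
#' `gain`), then the samples as little-endian int16 counts in line-major
#' order. Counts divided by `gain` recover physical amplitudes.
#'
#' @param frame A `qus_rf_frame`.
#' @param path File path.
#' @return `write_rf()` returns `path` invisibly; `read_rf()` returns the
#'   `qus_rf_frame`.
#' @export
write_rf <- function(frame, path) {
  stopifnot(inherits(frame, "qus_rf_frame"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("QUSRF1\n"), con)
  meta <- jsonlite::toJSON(list(
    n_lines = nrow(frame$lines), n_samples = ncol(frame$lines),
    sampling_rate_mhz = frame$sampling_rate,
    line_pitch_mm = frame$line_pitch,
    sound_speed_mm_us = frame$sound_speed,
    kind = frame$kind, gain = frame$gain), auto_unbox = TRUE, digits = NA)
  writeBin(charToRaw(paste0(meta, "\n")), con)
  counts <- as.integer(round(t(frame$lines) * frame$gain))
  writeBin(counts, con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname write_rf
#' @export
read_rf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 7L)
  if (!identical(rawToChar(magic), "QUSRF1\n")) {
    stop_qustr("%s is not an RF container", path)
  }
  header <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop_qustr("truncated RF container header in %s", path)
    if (b == charToRaw("\n")) break
    header <- c(header, b)
  }
  meta <- jsonlite::fromJSON(rawToChar(header))
  counts <- readBin(con, "integer", n = meta$n_lines * meta$n_samples,
                    size = 2L, signed = TRUE, endian = "little")
  lines <- t(matrix(counts / meta$gain, nrow = meta$n_samples,
                    ncol = meta$n_lines))
  rf_frame(lines, sampling_rate = meta$sampling_rate_mhz,
           line_pitch = meta$line_pitch_mm,
           sound_speed = meta$sound_speed_mm_us,
           kind = meta$kind, gain = meta$gain)
}
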