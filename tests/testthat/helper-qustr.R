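# Shared fixtures, built in code.

default_pulse <- function() make_pulse(6, 0.5, 35, 2)

default_reference <- function(pulse = default_pulse()) {
  simulate_reference_echo(pulse, focal_depth = 15)
}

# the standard three-ROI plan used across spectral tests: gates of
# `gate` samples centered at the 15 mm focal depth, 20 lines each
default_rois <- function(gate = 192L, fs = 35) {
  span <- gate * 1.54 / (2 * fs)
  lapply(c(2L, 22L, 42L), function(fl) {
    roi_spec(15 - span / 2, span, first_line = fl, n_lines = 20L)
  })
}

# analyze one simulated tissue frame with the default chain
analyze_frame <- function(frame, reference = default_reference(),
                          rois = default_rois(), threshold_db = 6) {
  tumor_spectral_params(frame, reference, rois, threshold_db = threshold_db)
}

# binary disk mask helper for histology fixtures
disk_mask <- function(h, w, cy, cx, r) {
  m <- matrix(0L, h, w)
  yy <- row(m) - cy
  xx <- col(m) - cx
  m[yy^2 + xx^2 <= r^2] <- 1L
  m
}

# wrap a binary mask into an RGB field: mask pixels dark blue (I < 120),
# background white
mask_to_field <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  px <- array(250, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[mask > 0] <- c(70, 55, 135)[ch]
    px[, , ch] <- plane
  }
  he_field(px)
}
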