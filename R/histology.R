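#' H&E histology field
#'
#' A single high-power-field (HPF) photomicrograph: an 8-bit RGB raster
#' (values 0-255) with an optional magnification tag and physical pixel
#' size. Hematoxylin renders nuclei dark blue-purple; eosin renders
#' cytoplasm pink, which is what the HSI-threshold segmentation exploits.
#'
#' @param pixels Numeric array `height x width x 3`, values in 0-255.
#' @param magnification_tag Text tag such as `"400x"`.
#' @param pixel_size Physical pixel size in micrometres, or `NULL`.
#' @return An object of class `qus_he_field`.
#' @export
he_field <- function(pixels, magnification_tag = "400x", pixel_size = NULL) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    stop_qustr("pixels must be a height x width x 3 RGB array")
  }
  if (d[1] < 64L || d[2] < 64L) {
    stop_qustr("field must be at least 64 x 64 pixels")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop_qustr("pixel values must lie in [0, 255]")
  }
  structure(list(pixels = pixels, magnification_tag = magnification_tag,
                 pixel_size = pixel_size),
            class = "qus_he_field")
}

#' Read/write a histology field as PNG
#'
#' @param path PNG file path.
#' @param field A `qus_he_field`.
#' @param ... Passed to [he_field()] when reading.
#' @return `read_he_field()` returns a `qus_he_field`; `write_he_field()`
#'   returns `path` invisibly.
#' @export
read_he_field <- function(path, ...) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]
  he_field(round(px * 255), ...)
}

#' @rdname read_he_field
#' @export
write_he_field <- function(field, path) {
  stopifnot(inherits(field, "qus_he_field"))
  png::writePNG(field$pixels / 255, path)
  invisible(path)
}

#' Nuclei segmentation parameters
#'
#' Thresholds of the Image-Pro-style counting procedure: inclusive HSI
#' ranges selecting stained pixels (the default intensity ceiling of 120
#' selects dark hematoxylin-stained nuclei), a minimum object area, the
#' allowed bounding-box width/height ratio, and whether touching nuclei are
#' separated by watershed splitting.
#'
#' @param hue_range,saturation_range,intensity_range Inclusive `c(lo, hi)`
#'   ranges on the 0-255 HSI scale.
#' @param area_min Minimum object area in pixels.
#' @param box_aspect_min,box_aspect_max Allowed bounding-box width/height
#'   ratio.
#' @param split_objects Separate touching nuclei by distance-transform
#'   watershed.
#' @param split_tolerance,split_ext Watershed `tolerance` (minimum basin
#'   depth, pixels of distance) and local-maximum neighbourhood radius;
#'   larger values merge nearby seeds, acting as a minimum seed separation.
#' @return An object of class `qus_seg_params`.
#' @export
seg_params <- function(hue_range = c(0, 255), saturation_range = c(0, 255),
                       intensity_range = c(0, 120), area_min = 50,
                       box_aspect_min = 0.5, box_aspect_max = 2,
                       split_objects = TRUE, split_tolerance = 1,
                       split_ext = 1) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] > 255) {
      stop_qustr("%s must be c(lo, hi) within [0, 255]", nm)
    }
  }
  chk(hue_range, "hue_range")
  chk(saturation_range, "saturation_range")
  chk(intensity_range, "intensity_range")
  if (area_min < 1) stop_qustr("area_min must be >= 1 pixel")
  if (box_aspect_min <= 0 || box_aspect_min > box_aspect_max) {
    stop_qustr("need 0 < box_aspect_min <= box_aspect_max")
  }
  structure(list(hue_range = hue_range, saturation_range = saturation_range,
                 intensity_range = intensity_range, area_min = area_min,
                 box_aspect_min = box_aspect_min,
                 box_aspect_max = box_aspect_max,
                 split_objects = isTRUE(split_objects),
                 split_tolerance = split_tolerance, split_ext = split_ext),
            class = "qus_seg_params")
}

#' RGB to Hue-Saturation-Intensity conversion on the 0-255 scale
#'
#' The standard arccos HSI formulation: intensity is the channel mean,
#' saturation is `1 - min/mean` (0 for gray and black), and hue is the
#' arccos angle mapped to 0-255 (0 when the denominator vanishes).
#'
#' @param field A `qus_he_field`, or a `height x width x 3` RGB array
#'   (0-255).
#' @return A `height x width x 3` array with planes H, S, I in 0-255.
#' @export
rgb_to_hsi <- function(field) {
  px <- if (inherits(field, "qus_he_field")) field$pixels else field
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0) * 255
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(pmin(pmax(ifelse(den > 0, 0.5 * ((r - g) + (r - b)) / den, 1),
                          -1), 1))
  h <- ifelse(b > g, 2 * pi - theta, theta)
  h[den == 0] <- 0
  out <- array(0, dim = dim(px))
  out[, , 1] <- pmin(pmax(h / (2 * pi) * 255, 0), 255)
  out[, , 2] <- pmin(pmax(s, 0), 255)
  out[, , 3] <- pmin(pmax(i, 0), 255)
  out
}

#' Threshold a field into a nucleus mask
#'
#' A pixel belongs to the mask iff its hue, saturation and intensity each
#' lie inside the configured inclusive ranges. With the defaults
#' (intensity <= 120) this selects the dark hematoxylin-stained nuclei and
#' rejects the bright eosin-stained background.
#'
#' @param field A `qus_he_field` or RGB array.
#' @param params A [seg_params()].
#' @return Integer matrix mask (1 = nucleus pixel), same size as the field.
#' @export
segment_nuclei <- function(field, params = seg_params()) {
  stopifnot(inherits(params, "qus_seg_params"))
  hsi <- rgb_to_hsi(field)
  inr <- function(x, r) x >= r[1] & x <= r[2]
  mask <- inr(hsi[, , 1], params$hue_range) &
    inr(hsi[, , 2], params$saturation_range) &
    inr(hsi[, , 3], params$intensity_range)
  matrix(as.integer(mask), nrow = nrow(mask))
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# only diagonally are merged afterwards with a union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]      # \ diagonal neighbours
  c1 <- lab[-nr, -1]; d <- lab[-1, -nc]     # / diagonal neighbours
  pairs <- rbind(
    cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
    cbind(c1[c1 > 0 & d > 0 & c1 != d], d[c1 > 0 & d > 0 & c1 != d]))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# per-label area and bounding-box extents of a labeled matrix
label_stats <- function(lab) {
  sel <- which(lab > 0, arr.ind = TRUE)
  if (nrow(sel) == 0L) {
    return(data.frame(label = integer(), area = integer(),
                      width = integer(), height = integer()))
  }
  lv <- lab[sel]
  data.frame(
    label = sort(unique(lv)),
    area = as.integer(table(lv)),
    width = as.integer(tapply(sel[, 2], lv, max) -
                         tapply(sel[, 2], lv, min) + 1),
    height = as.integer(tapply(sel[, 1], lv, max) -
                          tapply(sel[, 1], lv, min) + 1))
}

#' Label a mask and filter objects by area and box aspect
#'
#' Connected components are extracted with 8-connectivity; components whose
#' pixel area falls below `area_min` or whose bounding-box width/height
#' ratio falls outside `[box_aspect_min, box_aspect_max]` are discarded
#' (debris and slivers, per the printed thresholds: area >= 50 px, aspect
#' 0.5-2).
#'
#' @param mask Binary matrix from [segment_nuclei()].
#' @param params A [seg_params()].
#' @return Integer label matrix with surviving objects renumbered 1..K.
#' @export
label_and_filter <- function(mask, params = seg_params()) {
  stopifnot(inherits(params, "qus_seg_params"))
  lab <- label8(mask)
  st <- label_stats(lab)
  if (nrow(st) == 0L) return(lab)
  aspect <- st$width / st$height
  keep <- st$label[st$area >= params$area_min &
                     aspect >= params$box_aspect_min &
                     aspect <= params$box_aspect_max]
  out <- lab
  out[!(lab %in% keep)] <- 0L
  relab <- match(seq_len(max(lab)), sort(keep))
  out[out > 0] <- relab[out[out > 0]]
  out
}

#' Split touching nuclei by distance-transform watershed
#'
#' Each labeled object is re-segmented by a watershed on its Euclidean
#' distance transform; objects supporting a single seed pass through
#' unchanged, while merged clumps separate at the distance-map saddle
#' between their cores (the counterpart of a vendor "split objects"
#' function).
#'
#' @param labeled Integer label matrix (e.g. from [label_and_filter()]).
#' @param tolerance Minimum basin depth (distance-map units) for a separate
#'   seed; larger values merge nearby seeds.
#' @param ext Neighbourhood radius used for seed (local maximum) detection.
#' @return Integer label matrix with split objects renumbered.
#' @export
split_touching <- function(labeled, tolerance = 1, ext = 1) {
  if (max(labeled) == 0L) return(labeled)
  mask <- labeled > 0
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
  out <- matrix(as.integer(EBImage::imageData(ws)), nrow = nrow(labeled))
  # keep labels dense
  u <- sort(unique(out[out > 0]))
  out[out > 0] <- match(out[out > 0], u)
  out
}

#' Count nuclei in a field
#'
#' Runs the full chain: HSI segmentation, 8-connected labeling with
#' area/aspect filtering, then (optionally) watershed splitting of touching
#' nuclei; returns the number of surviving objects.
#'
#' @param field A `qus_he_field` or RGB array.
#' @param params A [seg_params()].
#' @return Integer nucleus count.
#' @export
count_field <- function(field, params = seg_params()) {
  lab <- label_and_filter(segment_nuclei(field, params), params)
  if (params$split_objects) {
    lab <- split_touching(lab, params$split_tolerance, params$split_ext)
  }
  max(lab)
}

#' Nuclei density over high-power fields
#'
#' Counts nuclei in each field and averages the counts, the per-tumor
#' histologic endpoint (conventionally the mean of ten 400x fields).
#'
#' @param fields List of `qus_he_field` objects (a warning is issued when
#'   not exactly 10).
#' @param params A [seg_params()].
#' @return An object of class `qus_nuclei_density`: list with
#'   `per_field_counts` and `mean_count`.
#' @export
density_per_hpf <- function(fields, params = seg_params()) {
  if (length(fields) == 0L) stop_qustr("at least one field is required")
  if (length(fields) != 10L) {
    warn_qustr("density is conventionally averaged over 10 fields, got %d",
               length(fields))
  }
  counts <- vapply(fields, count_field, numeric(1), params = params)
  structure(list(per_field_counts = counts, mean_count = mean(counts)),
            class = "qus_nuclei_density")
}

#' @export
print.qus_nuclei_density <- function(x, ...) {
  cat(sprintf("Nuclei density: %.2f per HPF (over %d fields)\n",
              x$mean_count, length(x$per_field_counts)))
  invisible(x)
}
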