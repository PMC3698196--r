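#' Synthesize an H&E-like field with known nucleus ground truth
#'
#' Draws `n_nuclei` dark blue-purple ellipses (hematoxylin-stained nuclei)
#' on a pink-white eosin-textured background. Nuclei are placed fully
#' inside the field; a requested fraction are placed as touching pairs to
#' exercise the split-objects step. Ellipse eccentricity and orientation
#' are jittered while keeping the bounding-box aspect within the default
#' filter gates, and all nucleus pixels fall below the intensity-120
#' threshold while the background stays above it, so the default
#' segmentation recovers the drawn nuclei.
#'
#' @param n_nuclei Number of nuclei to place (ground truth).
#' @param nucleus_radius_um Mean nucleus radius, micrometres (the ~15 um
#'   nuclear diameter of breast-carcinoma cells gives the default 7.5).
#' @param nucleus_radius_sd_um SD of the nucleus radius, micrometres.
#' @param overlap_fraction Fraction of nuclei placed as members of a
#'   touching pair (centre distance 1.6 radii).
#' @param image_size `c(height, width)` in pixels.
#' @param pixel_size_um Micrometres per pixel at 400x magnification.
#' @param seed Integer seed; fields are pure functions of their arguments.
#' @return List with `field` (a [he_field()]), `count` (ground-truth
#'   nucleus count) and `centers` (matrix of row/col centres).
#' @export
synthesize_he_field <- function(n_nuclei, nucleus_radius_um = 7.5,
                                nucleus_radius_sd_um = 0.8,
                                overlap_fraction = 0.08,
                                image_size = c(512, 512),
                                pixel_size_um = 0.8, seed = 1L) {
  stopifnot(n_nuclei >= 0, nucleus_radius_um > 0, nucleus_radius_sd_um >= 0,
            overlap_fraction >= 0, overlap_fraction <= 1)
  h <- as.integer(image_size[1]); wd <- as.integer(image_size[2])
  stopifnot(h >= 64L, wd >= 64L)
  r_px <- nucleus_radius_um / pixel_size_um
  r_sd_px <- nucleus_radius_sd_um / pixel_size_um
  # radius floor keeping every nucleus above the default 50 px area gate
  r_floor <- max(sqrt(50 / pi) / 0.93, r_px - 3 * r_sd_px)

  with_local_seed(seed, {
    px <- he_background(h, wd)
    if (n_nuclei == 0) {
      return(list(field = he_field(px, pixel_size = pixel_size_um),
                  count = 0L, centers = matrix(numeric(0), ncol = 2)))
    }
    radii <- pmax(rnorm(n_nuclei, r_px, r_sd_px), r_floor)
    n_pair <- floor(n_nuclei * overlap_fraction / 2)
    centers <- place_nuclei(n_nuclei, n_pair, radii, h, wd)
    is_pair <- logical(n_nuclei)
    if (n_pair > 0) is_pair[seq_len(2 * n_pair)] <- TRUE
    for (i in seq_len(n_nuclei)) {
      d <- draw_nucleus(h, wd, centers[i, 1], centers[i, 2], radii[i],
                        near_circular = is_pair[i])
      px[d$idx] <- d$val
    }
    list(field = he_field(px, pixel_size = pixel_size_um),
         count = as.integer(n_nuclei), centers = centers)
  })
}

# pink-white background with coarse eosin blotches and fine grain, all
# well above the intensity-120 nucleus threshold
he_background <- function(h, wd) {
  base <- c(246, 233, 238)
  px <- array(rep(base, each = h * wd), dim = c(h, wd, 3))
  # coarse eosin texture: smooth low-frequency pink modulation
  n_blotch <- round(h * wd / 3000)
  blotch <- matrix(0, h, wd)
  if (n_blotch > 0) {
    cy <- runif(n_blotch, 1, h); cx <- runif(n_blotch, 1, wd)
    amp <- runif(n_blotch, 0.3, 1)
    sg <- runif(n_blotch, 8, 20)
    for (b in seq_len(n_blotch)) {
      y0 <- max(1L, floor(cy[b] - 3 * sg[b]))
      y1 <- min(h, ceiling(cy[b] + 3 * sg[b]))
      x0 <- max(1L, floor(cx[b] - 3 * sg[b]))
      x1 <- min(wd, ceiling(cx[b] + 3 * sg[b]))
      gy <- exp(-((y0:y1) - cy[b])^2 / (2 * sg[b]^2))
      gx <- exp(-((x0:x1) - cx[b])^2 / (2 * sg[b]^2))
      blotch[y0:y1, x0:x1] <- blotch[y0:y1, x0:x1] + amp[b] * outer(gy, gx)
    }
    blotch <- blotch / max(blotch)
  }
  px[, , 1] <- px[, , 1] - 8 * blotch
  px[, , 2] <- px[, , 2] - 45 * blotch
  px[, , 3] <- px[, , 3] - 30 * blotch
  grain <- matrix(rnorm(h * wd, 0, 3), h, wd)
  for (ch in 1:3) px[, , ch] <- px[, , ch] + grain
  pmin(pmax(px, 150), 255)
}

# sequential placement: pairs touch at 1.6 radii; everything else keeps a
# centre distance that guarantees disjoint nuclei when the field is sparse
# enough, relaxing toward dense packing (touching resolved by the watershed
# split) when the requested density demands it
place_nuclei <- function(n, n_pair, radii, h, wd) {
  r_max <- max(radii)
  margin <- 1.3 * r_max + 2
  sep_full <- 2 * 1.15 * r_max + 2          # disjoint even for worst ellipses
  sep_dense <- sqrt(0.38 * 4 * (h - 2 * margin) * (wd - 2 * margin) /
                      (max(n, 1) * pi))
  min_d <- max(min(sep_full, sep_dense), 1.9 * mean(radii))
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  min_sq <- min_d^2
  clear_of_placed <- function(pts, skip = 0L) {
    # rows of `pts` whose squared distance to every placed centre is >= min_sq
    if (placed == 0L) return(rep(TRUE, nrow(pts)))
    keep <- seq_len(placed)
    if (skip > 0L) keep <- keep[keep != skip]
    if (length(keep) == 0L) return(rep(TRUE, nrow(pts)))
    d2 <- outer(pts[, 1], centers[keep, 1], "-")^2 +
      outer(pts[, 2], centers[keep, 2], "-")^2
    apply(d2, 1, min) >= min_sq
  }
  propose <- function(k) {
    cbind(runif(k, margin, h - margin), runif(k, margin, wd - margin))
  }
  max_rounds <- 3000L
  rounds <- 0L
  bump <- function() {
    rounds <<- rounds + 1L
    if (rounds > max_rounds) {
      stop_qustr(paste0("could not place %d nuclei at this density; ",
                        "achieved maximum was %d"), n, placed)
    }
  }

  # touching pairs first: primary, then a partner at 1.6 radii
  for (j in seq_len(n_pair)) {
    i <- 2L * j - 1L
    repeat {
      bump()
      cand <- propose(60L)
      ok <- which(clear_of_placed(cand))
      if (length(ok) == 0L) next
      centers[i, ] <- cand[ok[1L], ]
      placed <- placed + 1L
      d <- 1.6 * mean(radii[c(i, i + 1L)])
      ang <- runif(40L, 0, 2 * pi)
      part <- cbind(centers[i, 1] + d * cos(ang), centers[i, 2] + d * sin(ang))
      inb <- part[, 1] >= margin & part[, 1] <= h - margin &
        part[, 2] >= margin & part[, 2] <= wd - margin
      okp <- which(inb & clear_of_placed(part, skip = placed))
      if (length(okp) > 0L) {
        centers[i + 1L, ] <- part[okp[1L], ]
        placed <- placed + 1L
        break
      }
      placed <- placed - 1L  # retract primary, retry the pair elsewhere
      centers[i, ] <- NA_real_
    }
  }

  # remaining singletons in vectorized batches: each batch is screened
  # against already-placed nuclei at once, then accepted greedily with a
  # check against members accepted earlier in the same batch
  i <- 2L * n_pair + 1L
  while (i <= n) {
    bump()
    cand <- propose(400L)
    ok <- which(clear_of_placed(cand))
    placed0 <- placed
    for (k in ok) {
      if (i > n) break
      pt <- cand[k, ]
      if (placed > placed0) {
        batch <- centers[(placed0 + 1L):placed, , drop = FALSE]
        if (any((batch[, 1] - pt[1])^2 + (batch[, 2] - pt[2])^2 < min_sq)) {
          next
        }
      }
      centers[i, ] <- pt
      placed <- placed + 1L
      i <- i + 1L
    }
  }
  centers
}

# rasterize one elliptical nucleus as linear indices + values into an
# h x wd x 3 array (assigned by the caller, avoiding array copies);
# `near_circular` keeps touching pairs within the bounding-box aspect gate
draw_nucleus <- function(h, wd, cy, cx, r, near_circular = FALSE) {
  s <- if (near_circular) runif(1, 1, 1.05) else runif(1, 1, 1.15)
  a <- r * s; b <- r / s
  th <- runif(1, 0, pi)
  base <- c(70, 55, 135) + rnorm(3, 0, 6)
  y0 <- max(1L, floor(cy - a - 1)); y1 <- min(h, ceiling(cy + a + 1))
  x0 <- max(1L, floor(cx - a - 1)); x1 <- min(wd, ceiling(cx + a + 1))
  yy <- (y0:y1) - cy
  xx <- (x0:x1) - cx
  u <- outer(yy, rep(1, length(xx))) * cos(th) +
    outer(rep(1, length(yy)), xx) * sin(th)
  v <- -outer(yy, rep(1, length(xx))) * sin(th) +
    outer(rep(1, length(yy)), xx) * cos(th)
  inside <- which((u / a)^2 + (v / b)^2 <= 1)
  if (length(inside) == 0L) return(list(idx = integer(0), val = numeric(0)))
  # mild chromatin texture, clamped so intensity stays below the threshold
  tex <- (1 + 0.08 * ((u / a)^2 + (v / b)^2))[inside]
  rows <- ((inside - 1L) %% length(yy)) + y0
  cols <- ((inside - 1L) %/% length(yy)) + x0
  plane_idx <- (cols - 1L) * h + rows
  n_in <- length(inside)
  idx <- c(plane_idx, plane_idx + h * wd, plane_idx + 2L * h * wd)
  val <- c(pmin(pmax(base[1] * tex + rnorm(n_in, 0, 4), 25), 110),
           pmin(pmax(base[2] * tex + rnorm(n_in, 0, 4), 25), 110),
           pmin(pmax(base[3] * tex + rnorm(n_in, 0, 4), 25), 110))
  list(idx = idx, val = val)
}
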