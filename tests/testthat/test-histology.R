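test_that("HSI conversion matches the arccos formulation on primary colors", {
  px <- array(0, dim = c(64, 64, 3))
  # gray field
  px[, , 1] <- 120; px[, , 2] <- 120; px[, , 3] <- 120
  hsi <- rgb_to_hsi(px)
  expect_true(all(hsi[, , 2] == 0))
  expect_true(all(hsi[, , 3] == 120))
  # black
  hsi0 <- rgb_to_hsi(array(0, dim = c(64, 64, 3)))
  expect_true(all(hsi0[, , 2] == 0))
  expect_true(all(hsi0[, , 3] == 0))
  # pure blue: hue = 4 pi / 3 on the circle -> 170 on the 0-255 scale
  pb <- array(0, dim = c(64, 64, 3)); pb[, , 3] <- 255
  hsib <- rgb_to_hsi(pb)
  expect_equal(hsib[1, 1, 1], 170, tolerance = 0.5)
  expect_equal(hsib[1, 1, 3], 85)
})

test_that("white fields segment to an empty mask and blank fields count zero", {
  white <- he_field(array(255, dim = c(64, 64, 3)))
  expect_true(all(segment_nuclei(white) == 0))
  expect_equal(count_field(white), 0L)
  blank <- synthesize_he_field(0, seed = 1)
  expect_equal(blank$count, 0L)
  expect_equal(count_field(blank$field), 0L)
})

test_that("segmentation recovers the drawn nucleus area", {
  fld <- synthesize_he_field(12, overlap_fraction = 0, seed = 2)
  mask <- segment_nuclei(fld$field)
  # every nucleus pixel is below the intensity threshold by construction;
  # mask area within 5% of the drawn ellipse areas (r ~ 9.4 px)
  r_px <- 7.5 / 0.8
  expect_lt(abs(sum(mask) - 12 * pi * r_px^2), 0.10 * 12 * pi * r_px^2)
})

test_that("area and box-aspect filters match the printed thresholds", {
  # 40 px blob is below the 50 px area minimum
  m40 <- disk_mask(64, 64, 32, 32, 3.5)
  expect_lt(sum(m40), 50)
  expect_equal(max(label_and_filter(m40)), 0L)
  # 10 x 60 bar has aspect 6 > 2
  bar <- matrix(0L, 100, 100)
  bar[45:54, 20:79] <- 1L
  expect_equal(max(label_and_filter(bar)), 0L)
  # two disjoint 100+ px disks survive
  two <- disk_mask(128, 128, 32, 32, 6) + disk_mask(128, 128, 90, 90, 6)
  expect_equal(max(label_and_filter(two)), 2L)
})

test_that("labeling is 8-connected", {
  m <- matrix(0L, 64, 64)
  m[10, 10] <- 1L
  m[11, 11] <- 1L   # touches only diagonally
  expect_equal(max(qustr:::label8(m)), 1L)
})

test_that("filter monotonicity: tightening gates never increases the count", {
  fld <- synthesize_he_field(40, seed = 6)
  mask <- segment_nuclei(fld$field)
  counts <- sapply(c(10, 50, 150, 300), function(am) {
    max(label_and_filter(mask, seg_params(area_min = am)))
  })
  expect_true(all(diff(counts) <= 0))
  wide <- max(label_and_filter(mask, seg_params(box_aspect_min = 0.2,
                                                box_aspect_max = 5)))
  tight <- max(label_and_filter(mask, seg_params(box_aspect_min = 0.9,
                                                 box_aspect_max = 1.1)))
  expect_gte(wide, tight)
})

test_that("split_touching separates constructed overlapping geometries", {
  # single circle passes through unchanged
  one <- disk_mask(64, 64, 32, 32, 10)
  lab1 <- split_touching(label_and_filter(one))
  expect_equal(max(lab1), 1L)
  expect_equal(lab1 > 0, one > 0)
  # two equal circles overlapping by 20% of the radius
  r <- 10
  pair <- pmin(disk_mask(96, 96, 48, 38, r) + disk_mask(96, 96, 48, 38 + 1.8 * r, r), 1L)
  expect_equal(max(qustr:::label8(pair)), 1L)   # merged before the split
  expect_equal(max(split_touching(qustr:::label8(pair))), 2L)
  # dumbbell: two circles joined by a 1 px bridge
  db <- pmin(disk_mask(96, 96, 48, 25, 9) + disk_mask(96, 96, 48, 70, 9), 1L)
  db[48, 25:70] <- 1L
  expect_equal(max(qustr:::label8(db)), 1L)
  expect_equal(max(split_touching(qustr:::label8(db))), 2L)
})

test_that("split_touching is idempotent", {
  fld <- synthesize_he_field(60, overlap_fraction = 0.2, seed = 8)
  lab <- label_and_filter(segment_nuclei(fld$field))
  once <- split_touching(lab)
  twice <- split_touching(once)
  expect_equal(max(twice), max(once))
})

test_that("well-separated gate-compliant nuclei are counted exactly", {
  for (s in c(3, 13, 23)) {
    fld <- synthesize_he_field(12, overlap_fraction = 0, seed = s)
    expect_identical(count_field(fld$field), 12L)
  }
})

test_that("dense fields with overlaps are counted within 5%", {
  fld <- synthesize_he_field(300, overlap_fraction = 0.10, seed = 11)
  expect_lt(abs(count_field(fld$field) - 300), 0.05 * 300)
})

test_that("density per HPF averages the per-field counts", {
  flds <- lapply(c(31, 32, 33), function(s) {
    synthesize_he_field(20, overlap_fraction = 0, seed = s)$field
  })
  expect_warning(d <- density_per_hpf(flds), "10 fields")
  expect_equal(d$mean_count, mean(d$per_field_counts))
  expect_equal(d$per_field_counts, rep(20, 3))
  expect_error(density_per_hpf(list()), "at least one")
})

test_that("generator and counter agree for both group parameterizations", {
  count_group <- function(target, seed0) {
    flds <- lapply(1:6, function(k) {
      synthesize_he_field(round(target), seed = seed0 + k)$field
    })
    suppressWarnings(density_per_hpf(flds))$mean_count
  }
  expect_lt(abs(count_group(334.50, 400) - 334.5), 33.4)
  expect_lt(abs(count_group(78.51, 500) - 78.5), 7.8)
})

test_that("synthesized fields are reproducible and reject impossible densities", {
  a <- synthesize_he_field(30, seed = 12)
  b <- synthesize_he_field(30, seed = 12)
  expect_identical(a, b)
  expect_error(synthesize_he_field(4000, image_size = c(128, 128), seed = 1),
               "achieved maximum")
})

test_that("fields round-trip through PNG", {
  fld <- synthesize_he_field(10, seed = 14)$field
  path <- withr::local_tempfile(fileext = ".png")
  write_he_field(fld, path)
  back <- read_he_field(path)
  expect_equal(back$pixels, round(fld$pixels))
  expect_equal(count_field(back), count_field(fld))
})
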