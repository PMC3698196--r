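#' Configuration of a simulated treatment-response cohort
#'
#' Bundles everything needed to re-enact the study design in silico:
#' group sizes, the per-group distributions of the spectral ground truth
#' (slope, midband fit), nuclei density and calliper dimensions, the
#' acquisition settings (pulse, focal depth, frame geometry, noise), and
#' the histology generator settings. Defaults are the published group
#' statistics of the 12 + 12 animal study, so a default run reproduces the
#' study conditions at desk scale.
#'
#' Calliper dimensions are drawn per axis from a normal distribution whose
#' mean is the cube root of `6 * volume_mean / pi` (so mean volumes match)
#' and whose CV is the volume CV divided by `sqrt(3)` (delta method for a
#' product of three independent axes).
#'
#' @param n_per_group Tumors per group (>= 2).
#' @param group_params Printed group statistics, see
#'   [printed_group_params()].
#' @param pulse A [make_pulse()]; default 6 MHz, 50% bandwidth, 35 MHz
#'   sampling.
#' @param focal_depth Transducer focal depth, mm; ROIs center here.
#' @param n_lines,depth_span Frame geometry (lines, mm of depth).
#' @param noise_snr White-noise SNR of tissue frames, dB.
#' @param scatterer_density Scatterers per mm per line.
#' @param amplitude_cv Scatterer amplitude coefficient of variation.
#' @param n_fields H&E fields per tumor (HPF convention: 10).
#' @param nucleus_radius_um,nucleus_radius_sd_um Nucleus radius
#'   distribution, micrometres.
#' @param overlap_fraction Fraction of nuclei drawn as touching pairs.
#' @param image_size Histology field size `c(height, width)`, px.
#' @param seed Master seed; every per-sample draw derives from it.
#' @return An object of class `qus_cohort_config`.
#' @export
cohort_config <- function(n_per_group = 12,
                          group_params = printed_group_params(),
                          pulse = make_pulse(),
                          focal_depth = 15,
                          n_lines = 64L, depth_span = 45,
                          noise_snr = 30,
                          scatterer_density = QUS_REF_SCATTERER_DENSITY,
                          amplitude_cv = 0.3,
                          n_fields = 10L,
                          nucleus_radius_um = 7.5,
                          nucleus_radius_sd_um = 0.8,
                          overlap_fraction = 0.08,
                          image_size = c(512L, 512L),
                          seed = 1L) {
  if (n_per_group < 2) stop_qustr("n_per_group must be >= 2")
  sds <- unlist(lapply(group_params, function(g) {
    vapply(g, `[`, numeric(1), 2)
  }))
  if (any(sds < 0)) stop_qustr("all group SDs must be >= 0")
  stopifnot(inherits(pulse, "qus_pulse"), focal_depth > 0, n_fields >= 1)
  structure(
    list(n_per_group = as.integer(n_per_group), group_params = group_params,
         pulse = pulse, focal_depth = focal_depth,
         n_lines = as.integer(n_lines), depth_span = depth_span,
         noise_snr = noise_snr, scatterer_density = scatterer_density,
         amplitude_cv = amplitude_cv, n_fields = as.integer(n_fields),
         nucleus_radius_um = nucleus_radius_um,
         nucleus_radius_sd_um = nucleus_radius_sd_um,
         overlap_fraction = overlap_fraction,
         image_size = as.integer(image_size), seed = as.integer(seed)),
    class = "qus_cohort_config")
}

# per-axis calliper distribution implied by a group's volume mean/SD
axis_params <- function(volume) {
  mean_d <- (6 * volume[1] / pi)^(1 / 3)
  cv <- if (volume[1] > 0) volume[2] / volume[1] else 0
  c(mean_d, mean_d * cv / sqrt(3))
}

# ground truth and raw data of one tumor; `sample_index` spans the cohort
simulate_sample <- function(config, group, sample_index) {
  gp <- config$group_params[[group]]
  seed0 <- derive_seed(config$seed, sample_index * 13L)
  truth <- with_local_seed(seed0, {
    ax <- axis_params(gp$volume)
    list(ss = rnorm(1, gp$ss[1], gp$ss[2]),
         mbf = rnorm(1, gp$mbf[1], gp$mbf[2]),
         nuclei = max(rnorm(1, gp$nuclei[1], gp$nuclei[2]), 5),
         dims = pmax(rnorm(3, ax[1], ax[2]), 0.05))
  })
  response <- tissue_response(
    true_slope = truth$ss, true_midband = truth$mbf,
    reference_frequency = config$pulse$center_frequency,
    scatterer_density = config$scatterer_density,
    amplitude_cv = config$amplitude_cv)
  frame <- simulate_tissue_frame(
    config$pulse, response,
    geometry = list(n_lines = config$n_lines,
                    depth_span = config$depth_span),
    noise_snr = config$noise_snr, seed = derive_seed(config$seed,
                                                     sample_index * 13L + 1L))
  field_counts <- with_local_seed(derive_seed(config$seed,
                                              sample_index * 13L + 2L),
                                  rpois(config$n_fields, truth$nuclei))
  fields <- lapply(seq_len(config$n_fields), function(k) {
    synthesize_he_field(
      field_counts[k],
      nucleus_radius_um = config$nucleus_radius_um,
      nucleus_radius_sd_um = config$nucleus_radius_sd_um,
      overlap_fraction = config$overlap_fraction,
      image_size = config$image_size,
      seed = derive_seed(config$seed, sample_index * 13L + 2L + k))$field
  })
  list(sample_id = sprintf("%s_%02d", group, sample_index),
       group = group, truth = truth, frame = frame, fields = fields,
       dims = truth$dims)
}

#' Simulate a full cohort of tumor samples
#'
#' Generates `n_per_group` bundles per group: a tissue RF frame, H&E field
#' images, calliper dimensions, and the shared quartz-flat reference echo.
#' The per-sample ground truth (true slope/midband, target nuclei density)
#' is retained alongside for validation. Fully reproducible from the config
#' seed.
#'
#' @param config A [cohort_config()].
#' @param dir Optional directory: when given, RF frames and PNG fields are
#'   written there and bundles carry file paths instead of in-memory
#'   objects (with a `manifest.csv` of samples).
#' @return List with `reference` (frame or path), `samples` (list of
#'   bundles) and `config`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "qus_cohort_config"))
  reference <- simulate_reference_echo(config$pulse, config$focal_depth,
                                       n_samples = frame_samples(config))
  groups <- rep(c("control", "treated"), each = config$n_per_group)
  samples <- lapply(seq_along(groups), function(i) {
    simulate_sample(config, groups[i], i)
  })
  out <- list(reference = reference, samples = samples, config = config)
  if (!is.null(dir)) out <- write_cohort(out, dir)
  out
}

frame_samples <- function(config) {
  round(2 * config$depth_span / QUS_SOUND_SPEED *
          config$pulse$sampling_rate)
}

# externalize a cohort: RF containers + PNGs + manifest.csv
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref_path <- file.path(dir, "reference.rf")
  write_rf(cohort$reference, ref_path)
  rows <- lapply(cohort$samples, function(s) {
    rf_path <- file.path(dir, paste0(s$sample_id, ".rf"))
    write_rf(s$frame, rf_path)
    fpaths <- vapply(seq_along(s$fields), function(k) {
      p <- file.path(dir, sprintf("%s_field%02d.png", s$sample_id, k))
      write_he_field(s$fields[[k]], p)
      p
    }, character(1))
    data.frame(sample_id = s$sample_id, group = s$group,
               rf_path = rf_path, ref_path = ref_path,
               histology_paths = paste(fpaths, collapse = ";"),
               length_cm = s$dims[1], width_cm = s$dims[2],
               depth_cm = s$dims[3])
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cohort$manifest <- manifest
  cohort
}
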