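#' Configuration of a full experiment run
#'
#' Combines the cohort simulation settings with the analysis settings: the
#' ROI plan (three ROIs of one gate length centered at the focal depth,
#' side by side in non-overlapping line blocks), the histology segmentation
#' parameters, the spectral band threshold and the statistics options.
#'
#' @param cohort A [cohort_config()].
#' @param seg A [seg_params()].
#' @param band_threshold_db Analysis-band threshold below the reference
#'   peak, dB.
#' @param gate_samples Gate length of each ROI, samples (the tissue
#'   simulator's midband normalization gate).
#' @param roi_lines Lines per ROI.
#' @param ttest `"pooled"` or `"welch"`.
#' @return An object of class `qus_run_config`.
#' @export
run_config <- function(cohort = cohort_config(), seg = seg_params(),
                       band_threshold_db = 6,
                       gate_samples = QUS_NORM_GATE_SAMPLES,
                       roi_lines = 20L,
                       ttest = "pooled") {
  stopifnot(inherits(cohort, "qus_cohort_config"),
            inherits(seg, "qus_seg_params"))
  if (3L * roi_lines > cohort$n_lines) {
    stop_qustr("frame has %d lines; 3 ROIs of %d lines do not fit",
               cohort$n_lines, roi_lines)
  }
  structure(list(cohort = cohort, seg = seg,
                 band_threshold_db = band_threshold_db,
                 gate_samples = as.integer(gate_samples),
                 roi_lines = as.integer(roi_lines), ttest = ttest),
            class = "qus_run_config")
}

# the three-ROI plan implied by a run config: gates centered at the focal
# depth, in three adjacent line blocks
roi_plan <- function(config) {
  ch <- config$cohort
  fs <- ch$pulse$sampling_rate
  span <- config$gate_samples * QUS_SOUND_SPEED / (2 * fs)
  depth_start <- ch$focal_depth - span / 2
  gap <- (ch$n_lines - 3L * config$roi_lines) %/% 4L
  lapply(0:2, function(k) {
    roi_spec(depth_start, span,
             first_line = gap + k * (config$roi_lines + gap),
             n_lines = config$roi_lines)
  })
}

# analyze one simulated sample bundle into a SampleRecord row
analyze_sample <- function(sample, reference, config) {
  rois <- roi_plan(config)
  sp <- tumor_spectral_params(sample$frame, reference, rois,
                              threshold_db = config$band_threshold_db)
  dens <- suppressWarnings(density_per_hpf(sample$fields, config$seg))
  # echogenicity proxy over the middle ROI rectangle, on a fixed display
  # reference so frames are comparable
  ch <- config$cohort
  start <- depth_to_sample(rois[[2]]$depth_start, ch$pulse$sampling_rate,
                           QUS_SOUND_SPEED)
  rect <- c(rois[[2]]$first_line, rois[[2]]$n_lines, start,
            config$gate_samples)
  gray <- mean_gray_intensity(sample$frame, rect,
                              ref_level = peak_envelope(reference),
                              gain_db = 25)
  data.frame(sample_id = sample$sample_id, group = sample$group,
             length_cm = sample$dims[1], width_cm = sample$dims[2],
             depth_cm = sample$dims[3],
             volume = tumor_volume(sample$dims[1], sample$dims[2],
                                   sample$dims[3]),
             gray_intensity = gray,
             slope = sp$slope, midband = sp$midband,
             nuclei_density = dens$mean_count,
             true_slope = sample$truth$ss, true_midband = sample$truth$mbf,
             true_nuclei = sample$truth$nuclei)
}

#' Run the end-to-end experiment
#'
#' Simulates the cohort, runs the spectral chain (three-ROI calibrated
#' spectra, regression biomarkers), the histology chain (segmentation,
#' filtering, splitting, 10-field averaging), the volume and echogenicity
#' measurements, and assembles the statistical report. All artifacts are
#' written to `out_dir`: `cohort.csv` (per-sample records), `params.json`
#' (per-sample spectral/histology values), `report.json`, `manifest.json`
#' (config digest and seed) and `log.txt`. Identical config and seed give
#' byte-identical CSV/JSON artifacts.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [cohort_report()], invisibly; the records carry the
#'   per-sample ground truth columns for validation.
#' @export
run_experiment <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "qus_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  ch <- config$cohort
  say("stage reference: focal depth %g mm", ch$focal_depth)
  reference <- simulate_reference_echo(ch$pulse, ch$focal_depth,
                                       n_samples = frame_samples(ch))
  groups <- rep(c("control", "treated"), each = ch$n_per_group)
  records <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sample <- simulate_sample(ch, groups[i], i)
    rec <- tryCatch(
      analyze_sample(sample, reference, config),
      error = function(e) {
        say("stage analyze FAILED for %s: %s", sample$sample_id,
            conditionMessage(e))
        writeLines(log_lines, log_path)
        stop_qustr("stage analyze failed for sample %s: %s",
                   sample$sample_id, conditionMessage(e))
      })
    say("stage analyze: %s slope %.3f midband %.3f nuclei %.1f",
        rec$sample_id, rec$slope, rec$midband, rec$nuclei_density)
    records[[i]] <- rec
  }
  records <- do.call(rbind, records)
  say("stage report: %d records", nrow(records))
  report <- cohort_report(records, ttest = config$ttest)

  write.csv(records, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(seq_len(nrow(records)), function(i) as.list(records[i, ])),
    file.path(out_dir, "params.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report_to_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = ch$seed, config_md5 = config_digest(config)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(report)
}

# md5 of the serialized configuration (pulse samples included)
config_digest <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Replicate the experiment and summarize metric distributions
#'
#' Repeats the study `n_replicates` times under independent derived seeds
#' and summarizes the report metrics (LOOCV accuracy / sensitivity /
#' specificity and the percent changes of slope and midband fit) with
#' mean, SD and quantiles. `level = "features"` draws the per-tumor
#' biomarkers directly from the group distributions (the distributional
#' layer of the simulator; fast, used for large replicate counts);
#' `level = "full"` runs the entire RF + histology pipeline per replicate.
#'
#' @param config A [run_config()].
#' @param n_replicates Number of replicates (>= 2).
#' @param level `"features"` or `"full"`.
#' @param seed Master seed (defaults to the cohort seed).
#' @return An object of class `qus_replication`: list with `summary` (data
#'   frame: metric, mean, sd, q025, median, q975) and `metrics` (matrix of
#'   per-replicate values).
#' @export
replication_study <- function(config = run_config(), n_replicates = 1000,
                              level = c("features", "full"), seed = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(config, "qus_run_config"), n_replicates >= 2)
  if (is.null(seed)) seed <- config$cohort$seed
  ch <- config$cohort
  one <- function(r) {
    if (level == "features") {
      coh <- simulate_feature_cohort(ch$n_per_group, ch$group_params,
                                     seed = derive_seed(seed, r))
      cv <- loocv_classify(cbind(coh$slope, coh$midband), coh$group)
      cm <- colMeans(coh[coh$group == "control", c("slope", "midband")])
      tm <- colMeans(coh[coh$group == "treated", c("slope", "midband")])
      c(accuracy = cv$accuracy, sensitivity = cv$sensitivity,
        specificity = cv$specificity,
        ss_percent_change = percent_change(cm[["slope"]], tm[["slope"]]),
        mbf_percent_change = percent_change(cm[["midband"]], tm[["midband"]]))
    } else {
      cfg <- config
      cfg$cohort$seed <- derive_seed(seed, r)
      rep_dir <- file.path(tempdir(), sprintf("qustr_rep_%d", r))
      on.exit(unlink(rep_dir, recursive = TRUE), add = TRUE)
      rpt <- run_experiment(cfg, rep_dir)
      c(accuracy = rpt$loocv$accuracy, sensitivity = rpt$loocv$sensitivity,
        specificity = rpt$loocv$specificity,
        ss_percent_change = rpt$measures$slope$percent_change,
        mbf_percent_change = rpt$measures$midband$percent_change)
    }
  }
  metrics <- t(vapply(seq_len(n_replicates), one, numeric(5)))
  qs <- apply(metrics, 2, quantile, probs = c(0.025, 0.5, 0.975))
  summary <- data.frame(metric = colnames(metrics),
                        mean = colMeans(metrics),
                        sd = apply(metrics, 2, sd),
                        q025 = qs[1, ], median = qs[2, ], q975 = qs[3, ],
                        row.names = NULL)
  structure(list(summary = summary, metrics = metrics,
                 level = level, n_replicates = n_replicates),
            class = "qus_replication")
}

#' @export
print.qus_replication <- function(x, ...) {
  cat(sprintf("Replication study (%s level, %d replicates):\n",
              x$level, x$n_replicates))
  print(x$summary, digits = 4)
  invisible(x)
}
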