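#' Assemble the cohort-level statistical report
#'
#' Computes, for every measure present in the records (volume, gray
#' intensity, spectral slope, midband fit, nuclei density): per-group mean
#' and SD, the pooled-variance Student's t-test, and the
#' normality/variance-homogeneity checks; plus Pearson correlations of the
#' spectral biomarkers with nuclei density, the two-feature LOOCV linear
#' discriminant, and the percent change of the spectral biomarkers from
#' control to treated. Missing measures are marked absent rather than
#' failing.
#'
#' @param records Data frame with columns `sample_id`, `group`
#'   (control/treated) and any of `length_cm`, `width_cm`, `depth_cm`,
#'   `volume`, `gray_intensity`, `slope`, `midband`, `nuclei_density`.
#'   When the three calliper columns are present and `volume` is not, it is
#'   computed with [tumor_volume()].
#' @param ttest `"pooled"` (Student) or `"welch"`.
#' @return An object of class `qus_report`.
#' @export
cohort_report <- function(records, ttest = c("pooled", "welch")) {
  ttest <- match.arg(ttest)
  stopifnot(is.data.frame(records), "group" %in% names(records))
  if (!all(records$group %in% c("control", "treated"))) {
    stop_qustr("group must be 'control' or 'treated'")
  }
  if (min(table(records$group)) < 2) {
    stop_qustr("need at least 2 records per group")
  }
  if (!"volume" %in% names(records) &&
      all(c("length_cm", "width_cm", "depth_cm") %in% names(records))) {
    records$volume <- pi / 6 * records$length_cm * records$width_cm *
      records$depth_cm
  }
  measures <- intersect(
    c("volume", "gray_intensity", "slope", "midband", "nuclei_density"),
    names(records))
  ctrl <- records[records$group == "control", , drop = FALSE]
  trt <- records[records$group == "treated", , drop = FALSE]

  per_measure <- lapply(measures, function(m) {
    x <- ctrl[[m]]; y <- trt[[m]]
    if (anyNA(c(x, y))) return(list(absent = TRUE))
    tt <- two_sample_ttest(x, y, var_equal = ttest == "pooled")
    checks <- if (length(x) >= 3 && length(y) >= 3) {
      assumption_checks(x, y)
    } else {
      list(ks_p_x = NA_real_, ks_p_y = NA_real_, levene_p = NA_real_)
    }
    list(absent = FALSE,
         control_mean = mean(x), control_sd = sd(x),
         treated_mean = mean(y), treated_sd = sd(y),
         t = tt$t, p = tt$p,
         checks = checks,
         percent_change = if (mean(x) != 0) percent_change(mean(x), mean(y))
                          else NA_real_)
  })
  names(per_measure) <- measures

  correlations <- NULL
  if (all(c("slope", "midband", "nuclei_density") %in% measures) &&
      !anyNA(records$nuclei_density)) {
    correlations <- list(
      slope_nuclei = pearson_correlation(records$slope,
                                         records$nuclei_density),
      midband_nuclei = pearson_correlation(records$midband,
                                           records$nuclei_density))
  }

  loocv <- NULL
  if (all(c("slope", "midband") %in% measures) &&
      !anyNA(records$slope) && !anyNA(records$midband)) {
    loocv <- loocv_classify(cbind(records$slope, records$midband),
                            records$group)
  }

  structure(list(n = nrow(records),
                 n_per_group = table(records$group),
                 measures = per_measure,
                 correlations = correlations,
                 loocv = loocv,
                 records = records),
            class = "qus_report")
}

#' @export
print.qus_report <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort report: %d samples (%d control, %d treated)\n",
              x$n, x$n_per_group[["control"]], x$n_per_group[["treated"]]))
  for (m in names(x$measures)) {
    pm <- x$measures[[m]]
    if (isTRUE(pm$absent)) {
      cat(sprintf("  %-15s absent\n", m))
      next
    }
    cat(sprintf(
      "  %-15s control %8.3f +/- %.3f | treated %8.3f +/- %.3f | t = %.3f, p = %.4g\n",
      m, pm$control_mean, pm$control_sd, pm$treated_mean, pm$treated_sd,
      pm$t, pm$p))
  }
  if (!is.null(x$measures$slope) && !isTRUE(x$measures$slope$absent)) {
    cat(sprintf("  percent change: slope %+.1f%%, midband %+.1f%%\n",
                x$measures$slope$percent_change,
                x$measures$midband$percent_change))
  }
  if (!is.null(x$correlations)) {
    cat(sprintf(
      "  nuclei density vs slope r = %.3f (p = %.4g), vs midband r = %.3f (p = %.4g)\n",
      x$correlations$slope_nuclei$r, x$correlations$slope_nuclei$p,
      x$correlations$midband_nuclei$r, x$correlations$midband_nuclei$p))
  }
  if (!is.null(x$loocv)) {
    cat(sprintf(
      "  LOOCV (slope, midband): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
      100 * x$loocv$accuracy, 100 * x$loocv$sensitivity,
      100 * x$loocv$specificity))
  }
  invisible(x)
}

# flatten a report into plain lists for JSON export
report_to_list <- function(report) {
  ms <- lapply(report$measures, function(pm) {
    if (isTRUE(pm$absent)) return(list(absent = TRUE))
    pm$checks <- pm$checks[c("ks_p_x", "ks_p_y", "levene_p")]
    pm
  })
  out <- list(n = report$n,
              n_control = as.integer(report$n_per_group[["control"]]),
              n_treated = as.integer(report$n_per_group[["treated"]]),
              measures = ms)
  if (!is.null(report$correlations)) out$correlations <- report$correlations
  if (!is.null(report$loocv)) {
    out$loocv <- report$loocv[c("accuracy", "sensitivity", "specificity")]
  }
  out
}
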