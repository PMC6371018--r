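#' Phantom quality-control run
#'
#' End-to-end phantom workflow: rasterize the digital Jaszczak phantom,
#' simulate an acquisition, run Richardson-Lucy contrast recovery across
#' iterations while tracing the per-sphere contrast recovery coefficient
#' Q_H and the consecutive-estimate RMSE, select the stopping iteration from
#' the reference (largest) sphere, derive the phantom calibration factor
#' from the total reconstructed counts within the phantom boundary, and
#' report per-sphere activity estimates and percent errors.
#'
#' @param phantom a \code{phantom_spec}.
#' @param model an \code{acquisition_model}.
#' @param psf \code{psf_model} used for the recovery (the deconvolution
#'   assumes this response; it need not equal the simulated one).
#' @param max_iterations Richardson-Lucy updates to run.
#' @param reference_sphere label of the sphere driving iteration selection.
#' @param out_dir optional directory for a JSON report.
#' @return an object of class \code{phantom_qc_report}.
#' @export
run_phantom_qc <- function(phantom = jaszczak_phantom_spec(),
                           model = acquisition_model(),
                           psf = psf_model(model$psf_fwhm),
                           max_iterations = 15,
                           reference_sphere = NULL,
                           out_dir = NULL) {
  ras <- rasterize_phantom(phantom)
  true_ratio <- phantom$spheres[[1]]$concentration /
                phantom$background_concentration
  observed <- simulate_acquisition(ras$activity, model)
  sphere_labels <- names(phantom$spheres)
  if (is.null(reference_sphere)) {
    dia <- vapply(phantom$spheres, function(s) s$diameter, numeric(1))
    reference_sphere <- sphere_labels[which.max(dia)]
  }
  bg <- ras$truth_masks$background

  rl <- rl_deconvolve(observed, psf, max_iterations, keep = "all")
  qh_traces <- sapply(sphere_labels, function(lb)
    vapply(rl$estimates, q_h, numeric(1),
           sphere = ras$truth_masks[[lb]], background = bg,
           true_ratio = true_ratio))
  qh0 <- vapply(sphere_labels, function(lb)
    q_h(observed, ras$truth_masks[[lb]], bg, true_ratio), numeric(1))
  chosen <- select_iteration(qh_traces[, reference_sphere], rl$rmse_trace)
  recovered <- rl$estimates[[chosen]]

  # phantom CF: total reconstructed counts within the phantom boundary over
  # total true activity
  cf_phantom <- total_counts(observed, ras$truth_masks$body) /
                ras$total_activity_MBq
  act_img <- apply_cf(recovered, cf_phantom)
  sphere_err <- vapply(sphere_labels, function(lb)
    percent_error(ras$sphere_activity_MBq[[lb]],
                  voi_stats(act_img, ras$truth_masks[[lb]])$total),
    numeric(1))

  report <- structure(list(
    seed = model$seed, model = model, psf_fwhm = psf$fwhm,
    true_ratio = true_ratio,
    total_activity_MBq = ras$total_activity_MBq,
    cf_phantom = cf_phantom,
    chosen_iteration = chosen,
    reference_sphere = reference_sphere,
    qh_initial = qh0,
    qh_traces = qh_traces,
    qh_selected = qh_traces[chosen, ],
    rmse_trace = rl$rmse_trace,
    sphere_activity_true_MBq = ras$sphere_activity_MBq,
    sphere_percent_error = sphere_err,
    recovered = recovered, observed = observed,
    truth_masks = ras$truth_masks),
    class = "phantom_qc_report")
  if (!is.null(out_dir)) write_qc_report(report, out_dir)
  report
}

#' @export
print.phantom_qc_report <- function(x, ...) {
  cat(sprintf(
    "<phantom_qc_report> CF = %.0f cps/MBq, iteration %d selected on %s\n",
    x$cf_phantom, x$chosen_iteration, x$reference_sphere))
  tab <- data.frame(sphere = names(x$qh_initial),
                    qh_initial = round(x$qh_initial, 1),
                    qh_selected = round(x$qh_selected, 1),
                    activity_error_pct = round(x$sphere_percent_error))
  print(tab, row.names = FALSE)
  invisible(x)
}

write_qc_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slim <- report[c("seed", "psf_fwhm", "true_ratio", "total_activity_MBq",
                   "cf_phantom", "chosen_iteration", "reference_sphere",
                   "qh_initial", "qh_selected", "rmse_trace",
                   "sphere_activity_true_MBq", "sphere_percent_error")]
  jsonlite::write_json(slim, file.path(out_dir, "phantom_qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_grid(report$recovered, file.path(out_dir, "recovered.nii.gz"))
  invisible(out_dir)
}

#' Cohort quantification run
#'
#' Full patient-style workflow on a (synthetic or supplied) cohort of paired
#' pre/post studies.  Stage order follows the quantitative protocol:
#' contrast recovery of the post-treatment image, calibration-factor fit of
#' liver counts on administered activity across the cohort, counts-to-MBq
#' conversion with per-patient percent error, Chan-Vese segmentation and
#' TLRs for both studies, voxel S-value dosimetry of the post study with
#' tumor/healthy dose summaries and cDVHs, and cohort statistics (Pearson
#' correlations, paired t on tumor volumes, Grubbs outlier screen on TLRs).
#'
#' @param cohort list of patients as returned by
#'   \code{\link{make_liver_cohort}}.
#' @param psf \code{psf_model} for contrast recovery.
#' @param recovery_iteration fixed stopping iteration for patient images
#'   (no phantom VOIs are available on a patient), typically calibrated by
#'   \code{\link{run_phantom_qc}}.
#' @param seg_params \code{chan_vese_params} for tumor delineation.
#' @param kernel \code{svalue_kernel} for dosimetry; NULL skips the dose
#'   stage.
#' @param half_life_h physical half-life, hours.
#' @param out_dir optional directory for a JSON report.
#' @return an object of class \code{cohort_report} with a per-patient table
#'   and cohort statistics.
#' @export
run_patient_quant <- function(cohort, psf = psf_model(12),
                              recovery_iteration = 6,
                              seg_params = chan_vese_params(),
                              kernel = NULL, half_life_h = 64.05,
                              out_dir = NULL) {
  n <- length(cohort)
  if (n < 1L) stop("empty cohort")
  use_dose <- !is.null(kernel)

  recovered <- vector("list", n)
  liver_counts <- administered <- numeric(n)
  for (i in seq_len(n)) {
    pat <- cohort[[i]]
    post <- pat$pair$study_b
    rec <- recover_contrast(post$spect, psf,
                            max_iterations = recovery_iteration,
                            fixed_iteration = recovery_iteration)
    recovered[[i]] <- rec$final
    liver_counts[i] <- total_counts(rec$final,
                                    post$ct_masks$liver)
    administered[i] <- pat$administered_MBq
  }
  cal <- fit_calibration(administered, liver_counts, method = "liver_voi")

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- cohort[[i]]
    pre <- pat$pair$study_a; post <- pat$pair$study_b
    liver <- post$ct_masks$liver
    act_img <- apply_cf(recovered[[i]], cal$slope)
    est <- voi_stats(act_img, liver)$total
    err <- percent_error(pat$administered_MBq, est)

    pre_rec <- recover_contrast(pre$spect, psf,
                                max_iterations = recovery_iteration,
                                fixed_iteration = recovery_iteration)
    pre_study <- study_set(pre_rec$final, pre$ct_masks,
                           pre$administered_activity, agent = "MAA")
    post_study <- study_set(recovered[[i]], post$ct_masks,
                            post$administered_activity, agent = "Y90")
    cmp <- compare_pre_post(pre_study, post_study, liver,
                            params = seg_params)

    dose_row <- list(mean_tumor_Gy = NA_real_, mean_healthy_Gy = NA_real_)
    if (use_dose) {
      acum <- cumulated_activity(act_img, half_life_h)
      dm <- dose_convolve(acum, kernel, engine = "transform")
      ds <- dose_voi_summary(dm, cmp$segmentation_post$tumor,
                             cmp$segmentation_post$healthy)
      dose_row <- ds[c("mean_tumor_Gy", "mean_healthy_Gy")]
    }
    rows[[i]] <- data.frame(
      patient = i, administered_MBq = pat$administered_MBq,
      estimated_MBq = est, percent_error = err,
      tlr_pre = cmp$tlr_pre, tlr_post = cmp$tlr_post,
      true_tlr = if (!is.null(pat$true_tlr)) pat$true_tlr else NA_real_,
      volume_pre_ml = cmp$volume_pre_ml, volume_post_ml = cmp$volume_post_ml,
      mean_tumor_Gy = dose_row$mean_tumor_Gy,
      mean_healthy_Gy = dose_row$mean_healthy_Gy)
  }
  tab <- do.call(rbind, rows)

  stats <- list(error = error_summary(tab$percent_error))
  if (n >= 3L) {
    stats$tlr_correlation <- pearson_r(tab$tlr_pre, tab$tlr_post)
    stats$volume_paired_t <- paired_t(tab$volume_pre_ml, tab$volume_post_ml)
    stats$tlr_outlier <- tryCatch(grubbs_max_outlier(tab$tlr_post),
                                  error = function(e) NULL)
    if (use_dose) {
      stats$dose_healthy_vs_activity <-
        pearson_r(tab$administered_MBq, tab$mean_healthy_Gy)
      stats$dose_tumor_vs_activity <-
        pearson_r(tab$administered_MBq, tab$mean_tumor_Gy)
    }
  }
  report <- structure(list(table = tab, calibration = cal, stats = stats,
                           recovery_iteration = recovery_iteration,
                           psf_fwhm = psf$fwhm),
                      class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(table = tab,
           cf = cal$slope, cf_ci95 = cal$slope_ci95,
           r_squared = cal$r_squared, stats = stats),
      file.path(out_dir, "cohort_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "<cohort_report> n = %d, CF = %.0f cps/MBq, mean error %.1f +/- %.1f %%\n",
    nrow(x$table), x$calibration$slope, x$stats$error$mean,
    x$stats$error$sd))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Load a run configuration from a YAML/JSON file
#'
#' Thin helper for scripted runs: reads a key-value configuration (YAML when
#' the \code{yaml} package is available, JSON otherwise) and returns it as a
#' named list; missing keys fall back to \code{defaults}.
#'
#' @param path configuration file.
#' @param defaults named list of fallback values.
#' @export
read_run_config <- function(path, defaults = list()) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  }
  utils::modifyList(defaults, cfg)
}
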