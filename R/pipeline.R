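#' Configuration for a full simulate-and-analyse run
#'
#' Bundles every knob of the pipeline: the root seed, cohort structure,
#' acquisition and task parameters, HRF, fit windows, the serial QC
#' thresholds (30/12 Hz linewidths, NAA SNR 20, 5 x MAD outliers), the
#' mixed-model residual filter (2.5 x MAD), the DFFITS screen
#' (2 sqrt(k/n)), stage toggles and an optional output directory.
#'
#' @param seed Root seed; every random stream derives from it.
#' @param cohort A [cohort_config()].
#' @param params An [acq_params()].
#' @param design A [task_design()].
#' @param hrf An [hrf_params()].
#' @param thresholds Named list: `fwhm_max_gaba_hz`, `fwhm_max_naa_hz`,
#'   `snr_min`, `outlier_mad`, `resid_mad`, `dffits_mult`.
#' @param stages Named logical vector toggling `deconvolve`, `bold`,
#'   `behaviour`, `stats`.
#' @param ideal_fwhm_hz Target linewidth for reference deconvolution when
#'   that stage is enabled.
#' @param output_dir Directory for CSV/JSON artefacts, or `NULL`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, cohort = cohort_config(),
                       params = acq_params(), design = task_design(),
                       hrf = hrf_params(),
                       thresholds = list(fwhm_max_gaba_hz = 30,
                                         fwhm_max_naa_hz = 12,
                                         snr_min = 20, outlier_mad = 5,
                                         resid_mad = 2.5, dffits_mult = 2),
                       stages = c(deconvolve = FALSE, bold = TRUE,
                                  behaviour = TRUE, stats = TRUE),
                       ideal_fwhm_hz = 6, output_dir = NULL) {
  stopifnot(all(unlist(thresholds) > 0))
  cfg <- list(seed = as.integer(seed), cohort = cohort, params = params,
              design = design, hrf = hrf, thresholds = thresholds,
              stages = stages, ideal_fwhm_hz = ideal_fwhm_hz,
              output_dir = output_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full per-subject pipeline
#'
#' simulate -> register -> condition GLM -> (optional reference
#' deconvolution) -> peak fitting + QC -> water-linewidth BOLD estimate ->
#' behaviour, for one subject, deterministically derived from the run
#' seed.
#'
#' @param config A [run_config()].
#' @param truth The subject's [subject_truth()].
#' @param subject_id Identifier recorded in the outputs.
#' @param subject_index Index used to derive the subject's random stream
#'   from `config$seed`.
#' @return A list: `estimates` (one row per condition: water-scaled
#'   GABA+/Glx/NAA from the DIFF spectrum, edit-OFF NAA/Cr/Cho, QC
#'   metrics, `usable`), `bold` (a `bold_estimate` or `NULL`), `behav`
#'   (behavioural metrics or `NULL`), `water_area`, `registration`
#'   summary, and `timings` (seconds per stage).
#' @export
run_subject <- function(config, truth, subject_id = "S001",
                        subject_index = 1L) {
  stopifnot(inherits(config, "run_config"))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  sub_seed <- derive_seed(config$seed, subject_index)

  t0 <- tic()
  sched <- build_schedule(config$params, config$design, seed = sub_seed)
  series <- simulate_transients(sched, truth, config$params,
                                seed = sub_seed + 1L, hrf = config$hrf)
  timings["simulate"] <- tic() - t0

  t0 <- tic()
  regd <- register_spectra(series)
  timings["register"] <- tic() - t0

  t0 <- tic()
  cs <- fit_condition_glm(regd$series, regd$estimates)
  timings["condition_glm"] <- tic() - t0

  # mean registered water spectrum: reference for scaling (and, when the
  # stage is enabled, for lineshape matching)
  wr <- which(sched$is_wref & regd$estimates$usable)
  wmean <- fid_to_spectrum(colMeans(regd$series$fids[wr, , drop = FALSE]),
                           config$params)
  wfit <- fit_wref(wmean)
  water_area <- if (wfit$converged) wfit$area else NA_real_

  maybe_deconv <- function(sp) {
    if (!isTRUE(config$stages[["deconvolve"]]) || is.null(sp)) return(sp)
    reference_deconvolve(sp, wmean, config$ideal_fwhm_hz, config$params)
  }

  t0 <- tic()
  conds <- c(list(task_off = cs$diff_off_task, task_on = cs$diff_on_pooled),
             stats::setNames(cs$diff_bins, paste0("bin", 0:4)))
  eo <- list(task_off = cs$editoff_off_task, task_on = cs$editoff_on_pooled)
  rows <- list()
  for (cn in names(conds)) {
    sp <- maybe_deconv(conds[[cn]])
    if (is.null(sp)) next
    fit <- fit_diff(sp)
    row <- data.frame(subject_id = subject_id, condition = cn,
                      gaba_iu = NA_real_, glx_iu = NA_real_,
                      naa_diff_iu = NA_real_, naa_iu = NA_real_,
                      cr_iu = NA_real_, cho_iu = NA_real_,
                      gaba_fwhm_hz = NA_real_, naa_fwhm_hz = NA_real_,
                      naa_snr = NA_real_, reject_stage = "fit_failed",
                      reject_reason = "", usable = FALSE,
                      stringsAsFactors = FALSE)
    if (all(fit$converged) && !is.na(water_area)) {
      fit <- scale_to_iu(fit, water_area)
      qc <- compute_qc(fit, sp,
                       fwhm_max_gaba_hz = config$thresholds$fwhm_max_gaba_hz,
                       fwhm_max_naa_hz = config$thresholds$fwhm_max_naa_hz,
                       snr_min = config$thresholds$snr_min)
      row$gaba_iu <- fit$iu[fit$name == "gaba"]
      row$glx_iu <- fit$iu[fit$name == "glx"]
      row$naa_diff_iu <- fit$iu[fit$name == "naa"]
      row$gaba_fwhm_hz <- qc$gaba_fwhm_hz
      row$naa_fwhm_hz <- qc$naa_fwhm_hz
      row$naa_snr <- qc$naa_snr
      row$reject_stage <- qc$reject_stage
      row$reject_reason <- qc$reject_reason
      row$usable <- qc$reject_stage == "none"
      eosp <- if (cn %in% names(eo)) maybe_deconv(eo[[cn]]) else NULL
      if (!is.null(eosp)) {
        efit <- fit_editoff(eosp)
        if (all(efit$converged)) {
          efit <- scale_to_iu(efit, water_area)
          row$naa_iu <- efit$iu[efit$name == "naa"]
          row$cr_iu <- efit$iu[efit$name == "cr"]
          row$cho_iu <- efit$iu[efit$name == "cho"]
        }
      }
    }
    rows[[cn]] <- row
  }
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  timings["quantify"] <- tic() - t0

  bold <- NULL
  if (isTRUE(config$stages[["bold"]])) {
    t0 <- tic()
    lw <- fit_linewidth_series(regd$series)
    lw <- clean_series(lw, k_mad = config$thresholds$outlier_mad)
    reg_wr <- regd$estimates[sched$is_wref, , drop = FALSE]
    cov <- cbind(spike = as.numeric(reg_wr$spike_flag),
                 abs_freq = abs(reg_wr$freq_offset_hz),
                 abs_phase = abs(reg_wr$phase_deg))
    bold <- estimate_bold(lw, build_bold_regressor(sched, config$hrf),
                          covariates = cov)
    timings["bold"] <- tic() - t0
  }

  behav <- NULL
  if (isTRUE(config$stages[["behaviour"]])) {
    log <- simulate_behaviour(config$design, truth, seed = sub_seed + 2L)
    behav <- behavioural_metrics(log)
    behav$subject_id <- subject_id
  }

  list(subject_id = subject_id, estimates = estimates, bold = bold,
       behav = behav, water_area = water_area,
       registration = regd$estimates, timings = timings)
}

#' Run a whole simulated cohort through the pipeline
#'
#' Simulates the cohort, runs [run_subject()] for everyone, applies the
#' cohort-level MAD outlier stage ([reject_outliers()], per condition),
#' and fits the statistical battery: the baseline group x BOLD models, the
#' task-state mixed model for Glx and GABA+, the medication model, rank
#' tests on behaviour, and the skipped-Spearman BOLD method comparison.
#' Writes CSV tables and a JSON manifest when `config$output_dir` is set.
#'
#' @param config A [run_config()].
#' @param progress Print one line per subject?
#' @return A list (the results manifest): `subjects` (covariates +
#'   per-subject BOLD and behaviour), `estimates` (long table), `models`,
#'   `correlations`, `behaviour_tests`, `qc_counts`, `config_seed`.
#' @export
run_cohort <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  coh <- simulate_cohort(config$cohort, seed = config$seed)
  tab <- coh$subjects
  n <- nrow(tab)
  if (!n) stop("empty cohort", call. = FALSE)

  est_list <- vector("list", n)
  for (i in seq_len(n)) {
    res <- run_subject(config, coh$truths[[i]], tab$subject_id[i], i)
    est_list[[i]] <- res$estimates
    tab$bold_fmrs[i] <- if (!is.null(res$bold)) res$bold$delta_fwhm_hz else NA
    if (!is.null(res$behav)) {
      tab$ra[i] <- res$behav$ra
      tab$rt_s[i] <- res$behav$rt_s
      tab$ra_over_rt[i] <- res$behav$ra_over_rt
      tab$rt_slowing_s[i] <- res$behav$rt_slowing_s
      tab$ra_congruent[i] <- res$behav$ra_congruent
      tab$ra_incongruent[i] <- res$behav$ra_incongruent
      tab$rt_congruent_s[i] <- res$behav$rt_congruent_s
      tab$rt_incongruent_s[i] <- res$behav$rt_incongruent_s
    }
    if (progress)
      message(sprintf("[%s] done (%.1f s)", tab$subject_id[i],
                      sum(res$timings)))
  }
  estimates <- do.call(rbind, est_list)

  # cohort-level serial stage 3: MAD outliers within each condition
  estimates <- do.call(rbind, lapply(split(estimates, estimates$condition),
                                     reject_outliers,
                                     k = config$thresholds$outlier_mad))
  estimates <- estimates[order(estimates$subject_id, estimates$condition), ]
  rownames(estimates) <- NULL

  # baseline (task-OFF) estimates joined onto the subject table
  base <- estimates[estimates$condition == "task_off" & estimates$usable,
                    c("subject_id", "glx_iu", "gaba_iu", "naa_iu", "cr_iu",
                      "cho_iu")]
  tab <- merge(tab, base, by = "subject_id", all.x = TRUE, sort = FALSE)

  manifest <- list(subjects = tab, estimates = estimates,
                   qc_counts = table(estimates$reject_stage),
                   config_seed = config$seed)

  if (isTRUE(config$stages[["stats"]])) {
    long <- estimates[estimates$condition %in% c("task_off", "task_on") &
                        estimates$usable, ]
    long <- merge(long, tab[, c("subject_id", "group", "fgm", "age_y")],
                  by = "subject_id", sort = FALSE)
    manifest$models <- list(
      baseline_glx_fmri = fit_baseline_model(tab, "glx", "fmri"),
      baseline_glx_fmrs = fit_baseline_model(tab, "glx", "fmrs"),
      baseline_gaba_fmri = fit_baseline_model(tab, "gaba", "fmri"),
      mixed_glx_task = fit_mixed_model(long, "glx", "task_state"),
      mixed_gaba_task = fit_mixed_model(long, "gaba", "task_state"),
      medication_gaba = tryCatch(medication_model(tab),
                                 error = function(e) conditionMessage(e)))
    ok <- stats::complete.cases(tab[, c("bold_fmrs", "bold_fmri_z")])
    corr_or_msg <- function(g, k) tryCatch(
      skipped_spearman(tab$bold_fmrs[ok & tab$group == g],
                       tab$bold_fmri_z[ok & tab$group == g],
                       seed = derive_seed(config$seed, k)),
      error = function(e) conditionMessage(e))
    manifest$correlations <- list(
      bold_methods_control = corr_or_msg("control", 9001L),
      bold_methods_patient = corr_or_msg("patient", 9002L))
    bt <- list(
      ra_group = rank_tests(tab$ra[tab$group == "patient"],
                            tab$ra[tab$group == "control"]),
      ra_over_rt_group = rank_tests(tab$ra_over_rt[tab$group == "patient"],
                                    tab$ra_over_rt[tab$group == "control"]),
      rt_congruency = rank_tests(tab$rt_incongruent_s, tab$rt_congruent_s,
                                 paired = TRUE),
      ra_congruency = rank_tests(tab$ra_incongruent, tab$ra_congruent,
                                 paired = TRUE))
    ps <- vapply(bt, `[[`, numeric(1), "p")
    p_holm <- holm_adjust(ps)
    for (i in seq_along(bt)) bt[[i]]$p_holm <- p_holm[i]
    manifest$behaviour_tests <- bt
  }

  if (!is.null(config$output_dir)) write_manifest(manifest, config)
  manifest
}
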