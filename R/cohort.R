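#' Configuration for a simulated case-control cohort
#'
#' Encodes the statistical structure the downstream models assume: group
#' sizes, a baseline Glx offset in patients, per-group coupling between the
#' BOLD-fMRI covariate and baseline Glx (opposite signs by default), the
#' correlation between the BOLD-fMRI covariate and the true water-line
#' narrowing, task-locked metabolite dynamics, a medication effect on
#' GABA+, and covariate distributions. Defaults emulate a 51 + 51 cohort
#' with lower baseline Glx in patients, a negative control-group /
#' positive patient-group BOLD-Glx association, a ~6% task-ON Glx increase
#' with a stronger early-interval response, and patient symptom/medication
#' distributions typical of a hallucinating-psychosis sample.
#'
#' @param n_control,n_patient Group sizes (each >= 2).
#' @param glx_mean_control Control mean baseline Glx amplitude, i.u.
#' @param glx_group_offset Patient minus control baseline Glx, i.u.
#' @param glx_sd Between-subject SD of baseline Glx, i.u.
#' @param gaba_mean,gaba_sd GABA+ amplitude distribution, i.u.
#' @param bold_coupling_control,bold_coupling_patient Slope of baseline Glx
#'   on the (centred) BOLD-fMRI Z covariate, i.u. per Z, per group.
#' @param fmri_z_mean_control,fmri_z_mean_patient,fmri_z_sd BOLD-fMRI
#'   median-Z distribution per group.
#' @param fmrs_fmri_r_control,fmrs_fmri_r_patient Correlation between the
#'   BOLD-fMRI Z and the true water-line narrowing, per group.
#' @param narrowing_mean_hz,narrowing_sd_hz Water-line narrowing
#'   distribution (truncated at `0.05` Hz).
#' @param task_glx_frac,task_gaba_frac,early_bin_boost Task-locked
#'   fractional metabolite changes passed to [subject_truth()].
#' @param gaba_ddd_slope Increase of patient GABA+ per defined daily dose.
#' @param age_mean,age_sd Patient age distribution, years; controls are
#'   pair-matched within `age_match_y` years.
#' @param age_match_y Maximum pairwise age mismatch, years.
#' @param fgm_mean,fgm_sd Grey-matter fraction distribution.
#' @param noise_sd,drift_hz_per_min,base_fwhm_hz,pc_offset Acquisition
#'   contamination parameters forwarded to [subject_truth()].
#' @param spike_prob_control,spike_prob_patient Motion-spike probabilities
#'   (patients move more).
#' @param prop_sz Fraction of patients in the schizophrenia-spectrum (SZ)
#'   diagnostic subgroup; the rest are other-diagnosis (OD).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 51L, n_patient = 51L,
                          glx_mean_control = 15, glx_group_offset = -2.0,
                          glx_sd = 1.5,
                          gaba_mean = 2.5, gaba_sd = 0.3,
                          bold_coupling_control = -0.38,
                          bold_coupling_patient = 0.16,
                          fmri_z_mean_control = 2.0,
                          fmri_z_mean_patient = 1.5, fmri_z_sd = 1.0,
                          fmrs_fmri_r_control = 0.35,
                          fmrs_fmri_r_patient = 0,
                          narrowing_mean_hz = 0.5, narrowing_sd_hz = 0.15,
                          task_glx_frac = 0.06, task_gaba_frac = 0,
                          early_bin_boost = 0.037,
                          gaba_ddd_slope = 0.15,
                          age_mean = 31.8, age_sd = 9.3, age_match_y = 4,
                          fgm_mean = 0.55, fgm_sd = 0.06,
                          noise_sd = 0.5, drift_hz_per_min = 1,
                          base_fwhm_hz = 8, pc_offset = 0.05,
                          spike_prob_control = 0.01,
                          spike_prob_patient = 0.02,
                          prop_sz = 36 / 51) {
  cfg <- as.list(environment())
  cfg$n_control <- as.integer(n_control)
  cfg$n_patient <- as.integer(n_patient)
  class(cfg) <- "cohort_config"
  if (cfg$n_control < 2L || cfg$n_patient < 2L)
    stop("group sizes must be >= 2", call. = FALSE)
  cfg
}

#' Simulate a case-control cohort
#'
#' Draws per-subject ground truth ([subject_truth()]) and covariates with
#' the structure set by [cohort_config()], and optionally the full
#' transient series for every subject. Ages are pair-matched across groups
#' within `age_match_y` years. Per-subject random streams are derived from
#' the root seed with the documented splitting rule, so any subject's data
#' can be regenerated independently.
#'
#' @param config A [cohort_config()].
#' @param seed Integer root seed.
#' @param spectra If `TRUE`, also simulate every subject's transient series
#'   (memory-heavy for large cohorts; the pipeline regenerates series
#'   per-subject instead).
#' @param params,design Acquisition parameters and task design used when
#'   `spectra = TRUE`.
#' @return A list with `subjects` (one row per subject: id, group,
#'   subgroup, covariates, simulated BOLD-fMRI Z), `truths` (list of
#'   [subject_truth()]), and `series` (list of transient series or `NULL`).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            spectra = FALSE,
                            params = acq_params(), design = task_design()) {
  stopifnot(inherits(config, "cohort_config"))
  nc <- config$n_control
  np <- config$n_patient
  n <- nc + np

  tab <- with_seed(seed, {
    group <- c(rep("control", nc), rep("patient", np))
    age_p <- stats::rnorm(np, config$age_mean, config$age_sd)
    age_p <- pmax(18, pmin(65, age_p))
    # pairwise age matching: control i matched to patient i where possible
    age_c <- if (nc <= np) {
      age_p[seq_len(nc)] + stats::runif(nc, -config$age_match_y,
                                        config$age_match_y)
    } else {
      c(age_p + stats::runif(np, -config$age_match_y, config$age_match_y),
        stats::rnorm(nc - np, config$age_mean, config$age_sd))
    }
    age <- c(pmax(18, pmin(65, age_c)), age_p)

    fgm <- pmax(0.35, pmin(0.75, stats::rnorm(n, config$fgm_mean,
                                              config$fgm_sd)))
    z_mean <- ifelse(group == "control", config$fmri_z_mean_control,
                     config$fmri_z_mean_patient)
    z <- stats::rnorm(n, z_mean, config$fmri_z_sd)
    # water-line narrowing correlated with the fMRI Z covariate
    r <- ifelse(group == "control", config$fmrs_fmri_r_control,
                config$fmrs_fmri_r_patient)
    z_std <- (z - z_mean) / config$fmri_z_sd
    narrowing <- config$narrowing_mean_hz + config$narrowing_sd_hz *
      (r * z_std + sqrt(1 - r^2) * stats::rnorm(n))
    narrowing <- pmax(0.05, narrowing)

    glx_mu <- config$glx_mean_control +
      ifelse(group == "patient", config$glx_group_offset, 0)
    coupling <- ifelse(group == "control", config$bold_coupling_control,
                       config$bold_coupling_patient)
    amp_glx <- pmax(1, glx_mu + coupling * (z - z_mean) +
                      stats::rnorm(n, 0, config$glx_sd))

    # patient clinical profile
    subgroup <- rep("none", n)
    n_sz <- round(config$prop_sz * np)
    subgroup[nc + seq_len(np)] <- sample(c(rep("SZ", n_sz),
                                           rep("OD", np - n_sz)))
    panss_p3 <- ifelse(group == "patient",
                       pmin(7, pmax(3, round(stats::rnorm(n, 4.6, 0.8)))),
                       NA_real_)
    panss_pos <- ifelse(group == "patient",
                        pmax(7, stats::rnorm(n, 18.1, 5.2)), NA_real_)
    panss_neg <- ifelse(group == "patient",
                        pmax(7, stats::rnorm(n, 17.7, 7.4)), NA_real_)
    panss_total <- ifelse(group == "patient",
                          pmax(30, stats::rnorm(n, 69.7, 19.3)), NA_real_)
    ddd <- ifelse(group == "patient" & stats::runif(n) > 0.2,
                  stats::rgamma(n, shape = 1.2, scale = 1.35), 0)
    ddd[group == "control"] <- NA_real_
    # ~10% of prescribed patients are non-adherent, so medication status
    # and prescribed dose are not perfectly confounded
    is_active <- !is.na(ddd) & ddd > 0 & stats::runif(n) > 0.1

    # GABA+ association with the prescribed dose (not adherence-gated)
    amp_gaba <- pmax(0.5, stats::rnorm(n, config$gaba_mean, config$gaba_sd) +
                       ifelse(is.na(ddd), 0, config$gaba_ddd_slope * ddd))

    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)), group = group,
      subgroup = subgroup, age_y = age, fgm = fgm,
      panss_p3 = panss_p3, panss_pos = panss_pos, panss_neg = panss_neg,
      panss_total = panss_total, ddd = ddd, is_active = is_active,
      bold_fmri_z = z, amp_glx = amp_glx, amp_gaba = amp_gaba,
      bold_narrowing_hz = narrowing, stringsAsFactors = FALSE)
  })

  truths <- lapply(seq_len(n), function(i) {
    r <- tab[i, ]
    subject_truth(
      amp_gaba = r$amp_gaba, amp_glx = r$amp_glx,
      task_glx_frac = config$task_glx_frac,
      task_gaba_frac = config$task_gaba_frac,
      early_bin_boost = config$early_bin_boost,
      bold_narrowing_hz = r$bold_narrowing_hz,
      base_fwhm_hz = config$base_fwhm_hz,
      drift_hz_per_min = config$drift_hz_per_min,
      motion_spike_prob = if (r$group == "patient")
        config$spike_prob_patient else config$spike_prob_control,
      noise_sd = config$noise_sd, pc_offset = config$pc_offset,
      fgm = r$fgm, age_y = r$age_y, group = r$group,
      panss_p3 = r$panss_p3, panss_pos = r$panss_pos,
      panss_neg = r$panss_neg, panss_total = r$panss_total,
      ddd = r$ddd, is_active = r$is_active)
  })
  names(truths) <- tab$subject_id

  series <- NULL
  if (spectra) {
    series <- lapply(seq_len(n), function(i) {
      sub_seed <- derive_seed(seed, i)
      sched <- build_schedule(params, design, seed = sub_seed)
      simulate_transients(sched, truths[[i]], params, seed = sub_seed + 1L)
    })
    names(series) <- tab$subject_id
  }

  list(subjects = tab, truths = truths, series = series)
}
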