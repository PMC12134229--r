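#' Ground-truth parameters for one simulated subject
#'
#' Collects every quantity the simulator needs to generate a subject's
#' transient series, behaviour and covariates. Amplitudes are in the
#' arbitrary "institutional units" scale used throughout the package: with
#' the default water amplitude, water-scaled quantification
#' ([scale_to_iu()]) recovers Gaussian-line difference-spectrum amplitudes
#' on this same scale, so `amp_glx = 15` yields a measured Glx near
#' 15 i.u.
#'
#' @param amp_gaba GABA+ (GABA plus co-edited macromolecule) amplitude in
#'   the edit difference spectrum, i.u.
#' @param amp_glx Glx (glutamate + glutamine) amplitude, i.u.
#' @param amp_naa,amp_cr,amp_cho Edit-OFF singlet amplitudes, i.u.
#' @param amp_water Unsuppressed water amplitude, arbitrary.
#' @param mm_frac Fraction of the 3.0 ppm difference-spectrum area
#'   attributed to co-edited macromolecules (bookkeeping only; the
#'   simulated GABA+ line already includes it).
#' @param task_glx_frac Fractional Glx increase on task-ON transients.
#' @param task_gaba_frac Fractional GABA+ change on task-ON transients.
#' @param early_bin_boost Additional fractional Glx change applied when the
#'   stimulus-to-acquisition interval is below 0.183 s.
#' @param bold_narrowing_hz Peak water-line narrowing (Hz) at the top of the
#'   haemodynamic response; applied as a subtraction from `base_fwhm_hz`.
#' @param base_fwhm_hz Resting linewidth of every resonance, Hz.
#' @param drift_hz_per_min Linear frequency drift rate, Hz per minute.
#' @param motion_spike_prob Per-transient probability of a motion spike
#'   (extra frequency offset ~ N(0, 5 Hz) and phase ~ N(0, 20 deg)).
#' @param noise_sd SD of the complex Gaussian time-domain noise per point.
#' @param pc_offset Amplitude of the phase-cycle-locked DC artefact added to
#'   each metabolite FID with the receiver sign (nuisance term the
#'   preprocessing linear model is expected to remove).
#' @param fgm Grey-matter fraction of the voxel, in (0, 1).
#' @param age_y Age in years.
#' @param group `"control"` or `"patient"`.
#' @param panss_p3,panss_pos,panss_neg,panss_total PANSS symptom scores.
#' @param ddd Defined daily dose of antipsychotic medication.
#' @param is_active Medicated flag.
#' @param behav A list of behavioural generator parameters, see
#'   [simulate_behaviour()].
#'
#' @return An object of class `subject_truth`.
#' @export
subject_truth <- function(amp_gaba = 2.5, amp_glx = 15, amp_naa = 30,
                          amp_cr = 20, amp_cho = 6, amp_water = 100,
                          mm_frac = 0.5,
                          task_glx_frac = 0.06, task_gaba_frac = 0,
                          early_bin_boost = 0,
                          bold_narrowing_hz = 0.5, base_fwhm_hz = 8,
                          drift_hz_per_min = 1, motion_spike_prob = 0.01,
                          noise_sd = 0.5, pc_offset = 0.05,
                          fgm = 0.55, age_y = 31.5, group = "control",
                          panss_p3 = NA_real_, panss_pos = NA_real_,
                          panss_neg = NA_real_, panss_total = NA_real_,
                          ddd = NA_real_, is_active = FALSE,
                          behav = list()) {
  tr <- list(amp_gaba = amp_gaba, amp_glx = amp_glx, amp_naa = amp_naa,
             amp_cr = amp_cr, amp_cho = amp_cho, amp_water = amp_water,
             mm_frac = mm_frac,
             task_glx_frac = task_glx_frac, task_gaba_frac = task_gaba_frac,
             early_bin_boost = early_bin_boost,
             bold_narrowing_hz = bold_narrowing_hz,
             base_fwhm_hz = base_fwhm_hz,
             drift_hz_per_min = drift_hz_per_min,
             motion_spike_prob = motion_spike_prob,
             noise_sd = noise_sd, pc_offset = pc_offset,
             fgm = fgm, age_y = age_y, group = group,
             panss_p3 = panss_p3, panss_pos = panss_pos,
             panss_neg = panss_neg, panss_total = panss_total,
             ddd = ddd, is_active = is_active, behav = behav)
  class(tr) <- "subject_truth"
  validate_subject_truth(tr)
  tr
}

validate_subject_truth <- function(tr) {
  stopifnot(inherits(tr, "subject_truth"))
  num <- tr[vapply(tr, is.numeric, logical(1))]
  ok_val <- function(x) all((is.na(x) & !is.nan(x)) | is.finite(x))
  if (!all(vapply(num, ok_val, logical(1))))
    stop("non-finite subject_truth parameter", call. = FALSE)
  amps <- c(tr$amp_gaba, tr$amp_glx, tr$amp_naa, tr$amp_cr, tr$amp_cho,
            tr$amp_water)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (tr$fgm <= 0 || tr$fgm >= 1) stop("fgm must lie in (0, 1)", call. = FALSE)
  fr <- c(tr$task_glx_frac, tr$task_gaba_frac, tr$early_bin_boost)
  if (any(fr <= -0.5 | fr >= 0.5))
    stop("task fractions must lie in (-0.5, 0.5)", call. = FALSE)
  if (tr$bold_narrowing_hz < 0)
    stop("bold_narrowing_hz must be >= 0", call. = FALSE)
  if (!tr$group %in% c("control", "patient"))
    stop("group must be 'control' or 'patient'", call. = FALSE)
  invisible(tr)
}
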