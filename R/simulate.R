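# Parametric transient simulator: each FID is a sum of damped complex
# exponentials with literature chemical shifts. Metabolite singlets (NAA,
# Cr, Cho) and water are Lorentzian; the edited GABA+ line and the Glx
# pseudo-doublet are Gaussian, matching the shapes later used for fitting.

# resonance table: edit-state amplitude factors chosen so the difference
# spectrum (edit-ON minus edit-OFF) shows GABA+ at 3.01 ppm with amplitude
# amp_gaba, Glx at 3.71/3.79 ppm with summed-line amplitude amp_glx, and an
# inverted NAA lobe at 2.01 ppm (-0.5 * amp_naa); Cr and Cho cancel.
resonance_table <- function(truth) {
  data.frame(
    name   = c("naa", "cr", "cho", "gaba", "glx1", "glx2", "water"),
    ppm    = c(2.01, 3.03, 3.20, 3.01, 3.71, 3.79, 4.68),
    shape  = c("lorentz", "lorentz", "lorentz", "gauss", "gauss", "gauss",
               "lorentz"),
    amp    = c(truth$amp_naa, truth$amp_cr, truth$amp_cho, truth$amp_gaba,
               truth$amp_glx / 2, truth$amp_glx / 2, truth$amp_water),
    on_factor  = c(0.5, 1, 1, 1.0, 1.5, 1.5, 1),
    off_factor = c(1.0, 1, 1, 0.0, 0.5, 0.5, 1),
    task_mod   = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    is_water   = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Simulate a series of interleaved GABA-edited transients
#'
#' Generates one complex FID per scheduled transient. Each FID is a sum of
#' damped complex exponentials (see Details), with:
#' \itemize{
#'   \item instantaneous linewidth `base_fwhm_hz - bold_narrowing_hz * h(t)`
#'     where `h` is the HRF-convolved stimulus regressor normalised to
#'     peak 1 (BOLD activation narrows all lines);
#'   \item Glx amplitude scaled by `1 + task_glx_frac` on task-ON
#'     transients (plus `early_bin_boost` when `t_sa_s < 0.183`), GABA+ by
#'     `1 + task_gaba_frac`;
#'   \item linear frequency drift, motion spikes (random frequency/phase
#'     jumps), a phase-cycle-locked DC artefact on metabolite transients,
#'     and complex Gaussian noise.
#' }
#'
#' Water-unsuppressed reference transients contain only the water
#' resonance; metabolite transients contain NAA (2.01 ppm), Cr (3.03), Cho
#' (3.20), GABA+ (3.01, edit-ON only) and the Glx pseudo-doublet
#' (3.71/3.79) with edit-state amplitude factors such that the difference
#' spectrum shows positive GABA+ and Glx and an inverted NAA lobe.
#'
#' @param schedule An `acq_schedule` from [build_schedule()].
#' @param truth A [subject_truth()].
#' @param params The [acq_params()] used for the schedule.
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @param hrf [hrf_params()] governing the BOLD linewidth coupling.
#' @return A `transient_series`: list with complex FID matrix `fids`
#'   (transients in rows), `schedule`, `params`, `truth`, and a
#'   `transient_truth` data frame of per-transient ground truth (applied
#'   linewidth, frequency/phase errors, spike flags, amplitude scales).
#' @export
simulate_transients <- function(schedule, truth, params, seed = 1L,
                                hrf = hrf_params()) {
  validate_subject_truth(truth)
  validate_acq_params(params)
  n <- nrow(schedule)
  stopifnot(n == params$n_transients)
  t_s <- fid_time_s(params)

  # haemodynamic linewidth modulation, normalised to peak 1 over onsets
  events <- trial_onsets_s(schedule)
  h <- hrf_response(schedule$onset_s, events, hrf)
  if (length(h) && max(h) > 0) h <- h / max(h)
  fwhm_i <- truth$base_fwhm_hz - truth$bold_narrowing_hz * h
  if (any(fwhm_i <= 0)) stop("bold_narrowing_hz exceeds base_fwhm_hz")

  # task-state amplitude scaling
  task_on <- schedule$task_state == "ON"
  early <- task_on & !is.na(schedule$t_sa_s) & schedule$t_sa_s < 0.183
  glx_scale <- ifelse(task_on, 1 + truth$task_glx_frac, 1) +
    ifelse(early, truth$early_bin_boost, 0)
  gaba_scale <- ifelse(task_on, 1 + truth$task_gaba_frac, 1)

  # stochastic contamination
  rng <- with_seed(seed, {
    spike <- stats::runif(n) < truth$motion_spike_prob
    list(spike = spike,
         spike_f = ifelse(spike, stats::rnorm(n, 0, 5), 0),
         spike_p = ifelse(spike, stats::rnorm(n, 0, 20), 0),
         noise = if (truth$noise_sd > 0)
           matrix(complex(real = stats::rnorm(n * params$n_points, 0, truth$noise_sd),
                          imaginary = stats::rnorm(n * params$n_points, 0, truth$noise_sd)),
                  nrow = n) else NULL)
  })
  freq_err <- truth$drift_hz_per_min * schedule$onset_s / 60 + rng$spike_f
  phase_err_deg <- rng$spike_p

  res <- resonance_table(truth)
  amp_mat <- sapply(seq_len(nrow(res)), function(k) {
    r <- res[k, ]
    amp <- r$amp *
      ifelse(schedule$edit_state == "ON", r$on_factor, r$off_factor)
    if (r$task_mod) amp <- amp * (if (r$name == "gaba") gaba_scale
                                  else glx_scale)
    amp[schedule$is_wref != r$is_water] <- 0
    amp
  })
  carriers <- t(sapply(res$ppm, function(pp)
    exp(2i * pi * ppm_to_offset_hz(pp, params) * t_s)))

  # resonances sharing a decay shape are summed by one matrix product:
  # fids[rows, ] += envelope * (A %*% C), A = per-transient amplitudes,
  # C = complex carriers
  fids <- matrix(0 + 0i, nrow = n, ncol = params$n_points)
  for (shape in unique(res$shape)) {
    ks <- which(res$shape == shape)
    rows <- which(rowSums(amp_mat[, ks, drop = FALSE]) > 0)
    if (!length(rows)) next
    env <- if (shape == "lorentz") {
      exp(-pi * outer(fwhm_i[rows], t_s))
    } else {
      exp(-outer(fwhm_i[rows]^2, t_s^2) * pi^2 / (4 * log(2)))
    }
    A <- amp_mat[rows, ks, drop = FALSE]
    C <- carriers[ks, , drop = FALSE]
    fids[rows, ] <- fids[rows, ] + env * (A %*% C)
  }

  # frequency drift + motion spikes as time-dependent phase modulation
  mod_rows <- which(freq_err != 0 | phase_err_deg != 0)
  if (length(mod_rows)) {
    ph <- 2 * pi * outer(freq_err[mod_rows], t_s) +
      phase_err_deg[mod_rows] * pi / 180
    fids[mod_rows, ] <- fids[mod_rows, ] * exp(1i * ph)
  }

  # phase-cycle-locked DC artefact on metabolite transients
  if (truth$pc_offset != 0) {
    pc_sign <- ifelse(schedule$phase_step == 0, 1, -1)
    met <- which(!schedule$is_wref)
    fids[met, ] <- fids[met, ] + truth$pc_offset * pc_sign[met]
  }

  if (!is.null(rng$noise)) fids <- fids + rng$noise

  structure(list(
    fids = fids, schedule = schedule, params = params, truth = truth,
    transient_truth = data.frame(
      index = schedule$index, fwhm_hz = fwhm_i, hrf = h,
      freq_err_hz = freq_err, phase_err_deg = phase_err_deg,
      spike = rng$spike, glx_scale = glx_scale, gaba_scale = gaba_scale)),
    class = "transient_series")
}

#' @export
print.transient_series <- function(x, ...) {
  cat(sprintf("<transient_series> %d transients x %d points (%d wref)\n",
              nrow(x$fids), ncol(x$fids), sum(x$schedule$is_wref)))
  invisible(x)
}

# spectrum of one transient
transient_spectrum <- function(series, i) {
  fid_to_spectrum(series$fids[i, ], series$params)
}
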