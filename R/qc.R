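#' Quality metrics and the first two serial rejection stages
#'
#' Computes the NAA signal-to-noise ratio (fitted NAA amplitude over twice
#' the SD of the spectrum's real part in the signal-free 9.5-10.5 ppm
#' window) and evaluates the serial rejection criteria in order:
#' \enumerate{
#'   \item linewidth: GABA+ FWHM above 30 Hz or NAA FWHM above 12 Hz;
#'   \item SNR: NAA SNR strictly below 20 (evaluated only for spectra
#'     passing the linewidth stage).
#' }
#' The third (MAD outlier) stage operates across subjects and lives in
#' [reject_outliers()].
#'
#' @param diff_fit A converged [fit_diff()] result.
#' @param spectrum The DIFF [mrs_spectrum()] the fit came from.
#' @param fwhm_max_gaba_hz,fwhm_max_naa_hz,snr_min Rejection thresholds.
#' @param noise_window_ppm Signal-free window for the noise estimate.
#' @return A one-row data frame of class `qc_metrics`: `gaba_fwhm_hz`,
#'   `naa_fwhm_hz`, `naa_snr`, `reject_stage`
#'   (`"none"|"linewidth"|"snr"`), `reject_reason`.
#' @export
compute_qc <- function(diff_fit, spectrum,
                       fwhm_max_gaba_hz = 30, fwhm_max_naa_hz = 12,
                       snr_min = 20, noise_window_ppm = c(9.5, 10.5)) {
  sel <- spectrum$ppm_axis >= min(noise_window_ppm) &
    spectrum$ppm_axis <= max(noise_window_ppm)
  if (sum(sel) < 8L)
    stop("signal-free noise window not covered by the spectrum",
         call. = FALSE)
  noise_sd <- stats::sd(Re(spectrum$values[sel]))

  g <- diff_fit[diff_fit$name == "gaba", ]
  n <- diff_fit[diff_fit$name == "naa", ]
  if (!nrow(g) || !nrow(n) || !g$converged || !n$converged)
    stop("compute_qc requires converged GABA+ and NAA fits", call. = FALSE)
  naa_snr <- abs(n$amplitude) / (2 * max(noise_sd, 1e-300))

  stage <- "none"
  reason <- ""
  if (g$fwhm_hz > fwhm_max_gaba_hz || n$fwhm_hz > fwhm_max_naa_hz) {
    stage <- "linewidth"
    reason <- sprintf("GABA+ FWHM %.1f Hz (max %g) / NAA FWHM %.1f Hz (max %g)",
                      g$fwhm_hz, fwhm_max_gaba_hz, n$fwhm_hz,
                      fwhm_max_naa_hz)
  } else if (naa_snr < snr_min) {
    stage <- "snr"
    reason <- sprintf("NAA SNR %.1f below %g", naa_snr, snr_min)
  }
  out <- data.frame(gaba_fwhm_hz = g$fwhm_hz, naa_fwhm_hz = n$fwhm_hz,
                    naa_snr = naa_snr, reject_stage = stage,
                    reject_reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("qc_metrics", "data.frame")
  out
}

#' Third rejection stage: MAD outliers among surviving estimates
#'
#' For GABA+ and Glx independently, estimates surviving the linewidth and
#' SNR stages are rejected when they differ from the group median by more
#' than `k` times the (unscaled) median absolute deviation. A degenerate
#' all-identical group (MAD of zero) rejects nothing. Row order is
#' preserved; the stages already recorded in `reject_stage` are never
#' overwritten.
#'
#' @param estimates A data frame with columns `gaba_iu`, `glx_iu`,
#'   `reject_stage` (rows with `"none"` are the stage-1/2 survivors).
#' @param k Outlier multiplier (default 5).
#' @return The data frame with `reject_stage` set to `"outlier"` (and
#'   `usable` to `FALSE`, if present) for rejected rows.
#' @export
#' @examples
#' d <- data.frame(gaba_iu = c(10, 11, 12, 13, 50),
#'                 glx_iu = 15, reject_stage = "none")
#' reject_outliers(d)$reject_stage   # the 50 is rejected
reject_outliers <- function(estimates, k = 5) {
  surv <- which(estimates$reject_stage == "none")
  if (length(surv) < 3L) {
    warning("fewer than 3 stage-1/2 survivors; outlier stage skipped")
    return(estimates)
  }
  out <- rep(FALSE, nrow(estimates))
  for (col in c("gaba_iu", "glx_iu")) {
    x <- estimates[[col]][surv]
    med <- stats::median(x)
    mad_raw <- stats::median(abs(x - med))
    if (mad_raw == 0) next   # degenerate rule: no rejections
    out[surv] <- out[surv] | abs(x - med) > k * mad_raw
  }
  estimates$reject_stage[out] <- "outlier"
  if ("usable" %in% names(estimates)) estimates$usable[out] <- FALSE
  estimates
}

# documented water-scaling constant: with the simulator's default water
# amplitude (100), peak areas scale so that a difference-spectrum line of
# simulated amplitude a quantifies to a i.u.; hence default control Glx
# (amp 15) comes out near 15 i.u.
K_IU_DEFAULT <- 100

#' Water-scale fitted metabolite areas to institutional units
#'
#' `iu = area / water_area * k_iu`. The scale is arbitrary but documented:
#' the default `k_iu` makes the package simulator's default
#' healthy-control Glx quantify to about 15 i.u. No tissue or relaxation
#' corrections are applied.
#'
#' @param fit A `fit_result` from [fit_diff()] or [fit_editoff()].
#' @param water_area Fitted water peak area (same spectral scale), > 0.
#' @param k_iu Documented scaling constant.
#' @return The `fit_result` with an added `iu` column (signed: the
#'   inverted NAA difference-spectrum area stays negative).
#' @export
scale_to_iu <- function(fit, water_area, k_iu = K_IU_DEFAULT) {
  if (!is.numeric(water_area) || length(water_area) != 1L ||
      !is.finite(water_area) || water_area <= 0)
    stop("water_area must be a positive number", call. = FALSE)
  fit$iu <- fit$area / water_area * k_iu
  fit
}
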