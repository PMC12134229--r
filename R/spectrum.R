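#' Frequency-domain spectrum container
#'
#' A minimal container for a complex MRS spectrum. The ppm axis follows the
#' spectroscopy plotting convention: strictly decreasing left-to-right, i.e.
#' index 1 holds the highest chemical shift.
#'
#' @param values Complex vector of frequency-domain points.
#' @param ppm_axis Numeric vector of chemical shifts (ppm), strictly
#'   decreasing, same length as `values`.
#' @param f0_mhz Transmitter frequency in MHz (converts ppm to Hz).
#' @return An object of class `mrs_spectrum`.
#' @export
mrs_spectrum <- function(values, ppm_axis, f0_mhz) {
  stopifnot(length(values) == length(ppm_axis))
  if (any(diff(ppm_axis) >= 0))
    stop("ppm_axis must be strictly decreasing", call. = FALSE)
  structure(list(values = as.complex(values), ppm_axis = ppm_axis,
                 f0_mhz = f0_mhz),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d points, %.2f..%.2f ppm @ %.1f MHz\n",
              length(x$values), max(x$ppm_axis), min(x$ppm_axis), x$f0_mhz))
  invisible(x)
}

# time axis of an FID: t = (0:(N-1)) / spectral_width
fid_time_s <- function(params) {
  (seq_len(params$n_points) - 1L) / params$spectral_width_hz
}

fftshift <- function(x) {
  n <- length(x)
  c(x[(floor(n / 2) + 1L):n], x[1:floor(n / 2)])
}

ifftshift <- function(x) {
  n <- length(x)
  c(x[(ceiling(n / 2) + 1L):n], x[1:ceiling(n / 2)])
}

#' Transform a complex FID to an `mrs_spectrum`
#'
#' The carrier is assumed to sit on the water resonance
#' (`params$water_ppm`), so a time-domain component
#' \eqn{\exp(i 2 \pi f t)} appears at chemical shift
#' `water_ppm + f / f0_mhz`.
#'
#' @param fid Complex vector of `params$n_points` samples.
#' @param params An [acq_params()].
#' @return An [mrs_spectrum()].
#' @export
fid_to_spectrum <- function(fid, params) {
  stopifnot(length(fid) == params$n_points)
  # halve the first point: standard discrete correction so that flat
  # baselines come out flat and peak integrals match continuous lineshapes
  fid <- as.complex(fid)
  fid[1] <- fid[1] / 2
  spec <- fftshift(stats::fft(fid))
  n <- params$n_points
  f_hz <- (seq_len(n) - 1L - floor(n / 2)) / n * params$spectral_width_hz
  ppm <- params$water_ppm + f_hz / params$f0_mhz
  # reverse: spectroscopy convention, highest ppm first
  mrs_spectrum(rev(spec), rev(ppm), params$f0_mhz)
}

#' Inverse-transform an `mrs_spectrum` back to a complex FID
#'
#' Inverse of [fid_to_spectrum()] (including its first-point convention).
#'
#' @param spectrum An [mrs_spectrum()].
#' @param params The [acq_params()] used to create it.
#' @return Complex FID vector.
#' @export
spectrum_to_fid <- function(spectrum, params) {
  vals <- rev(spectrum$values)
  fid <- stats::fft(ifftshift(vals), inverse = TRUE) / length(vals)
  fid[1] <- fid[1] * 2
  fid
}

# frequency offset (Hz) of a chemical shift relative to the carrier
ppm_to_offset_hz <- function(ppm, params) {
  (ppm - params$water_ppm) * params$f0_mhz
}

# ---- lineshape primitives -------------------------------------------------

# time-domain decay envelopes for a line of given FWHM (Hz)
lorentz_envelope <- function(t, fwhm_hz) exp(-pi * fwhm_hz * t)
gauss_envelope <- function(t, fwhm_hz) exp(-(pi * fwhm_hz * t)^2 / (4 * log(2)))

# frequency-domain peak shapes (unit amplitude at centre)
lorentz_peak <- function(f_hz, center_hz, fwhm_hz) {
  1 / (1 + (2 * (f_hz - center_hz) / fwhm_hz)^2)
}
gauss_peak <- function(f_hz, center_hz, fwhm_hz) {
  exp(-4 * log(2) * ((f_hz - center_hz) / fwhm_hz)^2)
}
pseudo_voigt_peak <- function(f_hz, center_hz, fwhm_hz, eta) {
  eta * lorentz_peak(f_hz, center_hz, fwhm_hz) +
    (1 - eta) * gauss_peak(f_hz, center_hz, fwhm_hz)
}

# closed-form areas (amplitude x FWHM x shape constant)
lorentz_area <- function(amp, fwhm_hz) amp * fwhm_hz * pi / 2
gauss_area <- function(amp, fwhm_hz) amp * fwhm_hz * sqrt(pi / (4 * log(2)))

#' Measure the FWHM of the dominant peak in a ppm window
#'
#' Peak height and the two half-maximum crossings are located on the real
#' part by linear interpolation; intended for tests and diagnostics rather
#' than model fitting.
#'
#' @param spectrum An [mrs_spectrum()].
#' @param ppm_range Length-2 ppm window (any order) to search.
#' @param negative If `TRUE`, measure a negative-going peak.
#' @return FWHM in Hz.
#' @export
measure_fwhm_hz <- function(spectrum, ppm_range, negative = FALSE) {
  sel <- spectrum$ppm_axis >= min(ppm_range) & spectrum$ppm_axis <= max(ppm_range)
  if (sum(sel) < 5L) stop("ppm window too narrow for FWHM measurement")
  y <- Re(spectrum$values[sel])
  if (negative) y <- -y
  f_hz <- spectrum$ppm_axis[sel] * spectrum$f0_mhz  # decreasing
  ipk <- which.max(y)
  half <- y[ipk] / 2
  cross <- function(side_idx) {
    # walk outward from the peak until y drops below half, interpolate
    for (j in side_idx) {
      if (y[j] < half) {
        j0 <- j - sign(j - ipk)
        frac <- (y[j0] - half) / (y[j0] - y[j])
        return(f_hz[j0] + frac * (f_hz[j] - f_hz[j0]))
      }
    }
    NA_real_
  }
  left <- if (ipk > 1) cross(seq(ipk - 1L, 1L)) else NA_real_
  right <- if (ipk < length(y)) cross(seq(ipk + 1L, length(y))) else NA_real_
  if (is.na(left) || is.na(right))
    stop("half-maximum crossing outside the given window")
  abs(left - right)
}
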