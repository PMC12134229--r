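#' Pseudo-Voigt fit of an unsuppressed water spectrum
#'
#' Fits `eta * Lorentzian + (1 - eta) * Gaussian` (shared centre and FWHM)
#' plus a linear baseline to the real part of the spectrum within
#' `window_ppm` of the water resonance, by Levenberg-Marquardt least
#' squares.
#'
#' @param spectrum An [mrs_spectrum()] with a dominant water peak.
#' @param window_ppm Half-width of the fit window around the peak, ppm.
#' @return A list: `fwhm_hz`, `eta` (in `[0, 1]`), `amplitude`, `area`,
#'   `center_ppm`, `baseline` (intercept/slope), `converged`.
#' @export
fit_wref <- function(spectrum, window_ppm = 1.0) {
  f0 <- spectrum$f0_mhz
  pk_ppm <- spectrum$ppm_axis[which.max(Re(spectrum$values))]
  w <- fit_window(spectrum, pk_ppm + c(-window_ppm, window_ppm))
  st <- peak_start(w, fwhm0 = 8)
  fail <- list(fwhm_hz = NA_real_, eta = NA_real_, amplitude = NA_real_,
               area = NA_real_, center_ppm = NA_real_,
               baseline = c(NA_real_, NA_real_), converged = FALSE)
  if (is.null(st)) return(fail)
  fit <- fit_ls(
    function(p, f) p[1] * pseudo_voigt_peak(f, p[2], p[3], p[6]) + p[4] +
      p[5] * (f - mean(f)),
    par0 = c(a = st$a, c0 = st$c0, fw = st$fw, b0 = st$b0, b1 = 0,
             eta = 0.5),
    lower = c(0, min(w$f_hz), 0.2, -Inf, -Inf, 0),
    upper = c(Inf, max(w$f_hz), 100, Inf, Inf, 1), w = w)
  if (is.null(fit)) return(fail)
  cf <- fit$par
  list(fwhm_hz = cf[["fw"]], eta = cf[["eta"]], amplitude = cf[["a"]],
       area = cf[["eta"]] * lorentz_area(cf[["a"]], cf[["fw"]]) +
         (1 - cf[["eta"]]) * gauss_area(cf[["a"]], cf[["fw"]]),
       center_ppm = cf[["c0"]] / f0,
       baseline = c(cf[["b0"]], cf[["b1"]]), converged = TRUE)
}

#' Fit every water-reference transient, yielding the linewidth time series
#'
#' @param series A (registered) `transient_series`.
#' @return A data frame of class `linewidth_series`: `index`, `onset_s`,
#'   `fwhm_hz`, `eta`, `amplitude`, `area`, `valid` (convergence flag;
#'   cleaning in [clean_series()] may invalidate more).
#' @export
fit_linewidth_series <- function(series) {
  wr <- which(series$schedule$is_wref)
  rows <- lapply(wr, function(i) {
    f <- fit_wref(transient_spectrum(series, i))
    data.frame(index = series$schedule$index[i],
               onset_s = series$schedule$onset_s[i],
               fwhm_hz = f$fwhm_hz, eta = f$eta, amplitude = f$amplitude,
               area = f$area, valid = f$converged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("linewidth_series", "data.frame")
  out
}

#' Clean a water-linewidth series of outliers and discontinuities
#'
#' Two serial screens. First, outliers: samples deviating from the series
#' median by more than `k_mad` times the unscaled MAD are invalidated.
#' Second, discontinuities: on the remaining samples, any first difference
#' larger than `k_jump` times the MAD of all first differences invalidates
#' both adjacent samples. Both MAD estimates are floored at
#' `max(min_mad_hz, min_mad_frac * median linewidth)`: when the water fit
#' is very precise the raw MAD shrinks towards the fit noise, and without
#' the floor the screens would start flagging the genuine (sub-percent)
#' BOLD-driven linewidth dynamics rather than artefacts. Variation below a
#' few percent of the linewidth is physiological; discontinuities of
#' interest (motion, sudden shim changes) are far larger. No interpolation
#' is performed; invalid samples are simply excluded from the BOLD
#' regression.
#'
#' @param series A `linewidth_series`.
#' @param k_mad Outlier multiplier (default 5).
#' @param k_jump Jump multiplier on first differences (default 3).
#' @param min_mad_hz Absolute floor for both MAD estimates, Hz.
#' @param min_mad_frac Relative floor, as a fraction of the median
#'   linewidth.
#' @return The series with its `valid` flags updated; attribute
#'   `n_invalidated` records how many samples the cleaning removed.
#' @export
clean_series <- function(series, k_mad = 5, k_jump = 3, min_mad_hz = 0.01,
                         min_mad_frac = 0.025) {
  ok <- series$valid & is.finite(series$fwhm_hz)
  if (sum(ok) < 10L)
    warning("fewer than 10 valid linewidth samples before cleaning")
  x <- series$fwhm_hz
  med <- stats::median(x[ok])
  floor_hz <- max(min_mad_hz, min_mad_frac * med)
  mad_x <- max(stats::mad(x[ok], constant = 1), floor_hz)
  out <- ok & abs(x - med) > k_mad * mad_x

  idx <- which(ok & !out)   # jump rule runs on the outlier-cleaned series
  if (length(idx) > 2L) {
    d <- diff(x[idx])
    mad_d <- max(stats::mad(d, constant = 1), floor_hz)
    jump <- abs(d) > k_jump * mad_d
    bad <- unique(c(idx[which(jump)], idx[which(jump) + 1L]))
    out[bad] <- TRUE
  }
  series$valid <- ok & !out
  if (sum(series$valid) < 10L)
    warning("fewer than 10 valid linewidth samples after cleaning; ",
            "BOLD estimate will be unreliable")
  attr(series, "n_invalidated") <- sum(ok) - sum(series$valid)
  series
}

#' Estimate the BOLD response from the water-linewidth series
#'
#' Ordinary least squares of the cleaned linewidth on the HRF-convolved
#' task regressor plus covariates (intercept, linear drift, and any motion
#' columns supplied), over valid samples only. Activation narrows the
#' water line, so the reported BOLD strength is minus the regressor
#' coefficient: positive `delta_fwhm_hz` means a stronger BOLD response.
#'
#' @param series A cleaned `linewidth_series`.
#' @param regressor BOLD regressor sampled at the series' onsets
#'   ([build_bold_regressor()]).
#' @param covariates Optional numeric matrix/data frame of extra nuisance
#'   columns (e.g. standardised registration estimates for the
#'   water-reference transients), one row per series sample.
#' @return A list of class `bold_estimate`: `delta_fwhm_hz`, `se`,
#'   `tstat`, `p`, `n_used`, `reliable` (FALSE when fewer than 10 valid
#'   samples), and `sign_convention`.
#' @export
estimate_bold <- function(series, regressor, covariates = NULL) {
  stopifnot(length(regressor) == nrow(series))
  X <- cbind(bold = regressor, intercept = 1,
             drift = scale(series$onset_s)[, 1])
  ok <- series$valid & is.finite(series$fwhm_hz)
  qrX <- qr(X[ok, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient BOLD design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(covariates)) {
    # nuisance columns that are constant or collinear over the valid
    # samples carry no information and are pruned
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(series))
    for (j in seq_len(ncol(covariates))) {
      cand <- cbind(X, covariates[, j, drop = FALSE])
      if (qr(cand[ok, , drop = FALSE])$rank == ncol(cand)) X <- cand
    }
  }
  fit <- stats::lm(series$fwhm_hz[ok] ~ X[ok, , drop = FALSE] - 1)
  sm <- suppressWarnings(summary(fit))$coefficients
  rownames(sm) <- colnames(X)
  structure(list(
    delta_fwhm_hz = -sm["bold", "Estimate"],
    se = sm["bold", "Std. Error"],
    tstat = -sm["bold", "t value"],
    p = sm["bold", "Pr(>|t|)"],
    n_used = sum(ok),
    reliable = sum(ok) >= 10L,
    sign_convention = paste("activation narrows the water line;",
                            "delta_fwhm_hz = -(regressor coefficient),",
                            "larger = stronger BOLD")),
    class = "bold_estimate")
}

#' @export
print.bold_estimate <- function(x, ...) {
  cat(sprintf("<bold_estimate> dFWHM_water = %.3f Hz (SE %.3f, t = %.2f, n = %d)\n",
              x$delta_fwhm_hz, x$se, x$tstat, x$n_used))
  invisible(x)
}
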