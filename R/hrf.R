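#' Canonical dual-gamma haemodynamic response function parameters
#'
#' The standard double-gamma kernel: a gamma density peaking at
#' `peak_delay_s`, minus a later gamma density (the undershoot) scaled by
#' `1 / ratio`, truncated at `length_s`.
#'
#' @param peak_delay_s Time-to-peak of the positive lobe, seconds.
#' @param undershoot_delay_s Time-to-peak of the undershoot, seconds.
#' @param peak_disp,undershoot_disp Dispersions (gamma scale parameters).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Kernel support length, seconds.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_disp = 1, undershoot_disp = 1,
                       ratio = 6, length_s = 32) {
  stopifnot(peak_delay_s > 0, undershoot_delay_s > 0, ratio > 0,
            peak_disp > 0, undershoot_disp > 0, length_s > 0)
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, length_s = length_s),
            class = "hrf_params")
}

#' Evaluate the dual-gamma kernel
#'
#' @param t_s Times in seconds (vector).
#' @param hrf An [hrf_params()] object.
#' @return Kernel values; zero outside `[0, length_s]`.
#' @export
hrf_kernel <- function(t_s, hrf = hrf_params()) {
  h <- stats::dgamma(t_s, shape = hrf$peak_delay_s / hrf$peak_disp,
                     scale = hrf$peak_disp) -
    stats::dgamma(t_s, shape = hrf$undershoot_delay_s / hrf$undershoot_disp,
                  scale = hrf$undershoot_disp) / hrf$ratio
  h[t_s < 0 | t_s > hrf$length_s] <- 0
  h
}

# expected haemodynamic response at arbitrary times for unit impulses at
# event_s; exact superposition (impulse convolution evaluated directly)
hrf_response <- function(t_s, event_s, hrf = hrf_params()) {
  if (!length(event_s)) return(numeric(length(t_s)))
  out <- numeric(length(t_s))
  for (e in event_s) out <- out + hrf_kernel(t_s - e, hrf)
  out
}

#' Build the HRF-convolved BOLD regressor over water-reference onsets
#'
#' Unit impulses at the schedule's trial (stimulus) onsets are convolved
#' with the dual-gamma kernel and sampled at the onset times of the
#' water-unsuppressed reference transients, then normalised to peak 1.
#'
#' @param schedule An `acq_schedule` with trial events.
#' @param hrf An [hrf_params()] object.
#' @param at_s Optional sampling times; defaults to the water-reference
#'   transient onsets.
#' @return Numeric regressor, one value per sampling time, maximum 1.
#' @export
build_bold_regressor <- function(schedule, hrf = hrf_params(), at_s = NULL) {
  events <- trial_onsets_s(schedule)
  if (!length(events)) stop("schedule contains no trial events", call. = FALSE)
  if (is.null(at_s)) at_s <- schedule$onset_s[schedule$is_wref]
  r <- hrf_response(at_s, events, hrf)
  m <- max(r)
  if (m > 0) r <- r / m
  r
}
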