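# Shared fixtures: a coarser sampling grid (1024 points keeps the
# frequency resolution under 2 Hz at 2 kHz bandwidth) and a shortened
# two-block task design for tests that do not need the full 700-transient
# session.

test_params <- function(n_transients = 700L) {
  acq_params(n_points = 1024L, n_transients = n_transients)
}

mini_design <- function() task_design(n_on_blocks = 2L)

mini_params <- function() {
  d <- mini_design()
  acq_params(n_points = 1024L,
             n_transients = as.integer(design_duration_s(d) / 1.5))
}

quiet_truth <- function(...) {
  args <- utils::modifyList(
    list(noise_sd = 0, drift_hz_per_min = 0, motion_spike_prob = 0,
         pc_offset = 0, bold_narrowing_hz = 0), list(...))
  do.call(subject_truth, args)
}

# single-peak spectrum on the test grid, built directly from its FID
peak_spectrum <- function(shape = c("lorentz", "gauss"), fwhm_hz = 8,
                          amp = 1, ppm = 3.0, params = test_params(),
                          baseline_slope = 0, noise_sd = 0, seed = 1) {
  shape <- match.arg(shape)
  t_s <- (seq_len(params$n_points) - 1L) / params$spectral_width_hz
  env <- if (shape == "lorentz") exp(-pi * fwhm_hz * t_s) else
    exp(-(pi * fwhm_hz * t_s)^2 / (4 * log(2)))
  f_off <- (ppm - params$water_ppm) * params$f0_mhz
  fid <- amp * env * exp(2i * pi * f_off * t_s)
  sp <- fid_to_spectrum(fid, params)
  if (baseline_slope != 0)
    sp$values <- sp$values + baseline_slope * (sp$ppm_axis - ppm)
  if (noise_sd > 0) {
    set.seed(seed)
    sp$values <- sp$values + complex(real = rnorm(length(sp$values), 0, noise_sd),
                                     imaginary = rnorm(length(sp$values), 0, noise_sd))
  }
  sp
}
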