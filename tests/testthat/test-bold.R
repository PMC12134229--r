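test_that("pseudo-Voigt fit identifies pure Lorentzian and Gaussian lines", {
  p <- test_params()
  fl <- fit_wref(peak_spectrum("lorentz", fwhm_hz = 8, amp = 100,
                               ppm = 4.68, params = p))
  expect_true(fl$converged)
  expect_equal(fl$fwhm_hz, 8, tolerance = 0.05 / 8)
  expect_gte(fl$eta, 0.95)
  fg <- fit_wref(peak_spectrum("gauss", fwhm_hz = 8, amp = 100,
                               ppm = 4.68, params = p))
  expect_equal(fg$fwhm_hz, 8, tolerance = 0.05 / 8)
  expect_lte(fg$eta, 0.05)
})

test_that("a sloped baseline does not move the fitted linewidth", {
  p <- test_params()
  flat <- peak_spectrum("lorentz", fwhm_hz = 8, amp = 100, ppm = 4.68,
                        params = p)
  sloped <- peak_spectrum("lorentz", fwhm_hz = 8, amp = 100, ppm = 4.68,
                          params = p, baseline_slope = 40)
  f1 <- fit_wref(flat)
  f2 <- fit_wref(sloped)
  expect_lt(abs(f2$fwhm_hz - f1$fwhm_hz) / f1$fwhm_hz, 0.01)
})

test_that("series cleaning removes spikes and step discontinuities", {
  n <- 100L
  base <- data.frame(index = seq_len(n) * 3 - 1, onset_s = seq_len(n) * 4.5,
                     fwhm_hz = 8 + 0.001 * sin(seq_len(n)),
                     eta = 1, amplitude = 100, area = 1000, valid = TRUE)
  class(base) <- c("linewidth_series", "data.frame")
  # one gross spike: outlier stage takes it, jump stage sees a clean series
  s1 <- base
  s1$fwhm_hz[50] <- 10.5
  c1 <- clean_series(s1)
  expect_false(c1$valid[50])
  expect_equal(sum(!c1$valid), 1L)
  # clean series: nothing invalidated
  c0 <- clean_series(base)
  expect_equal(attr(c0, "n_invalidated"), 0L)
  # half-way step: survives the outlier screen (deviation well under
  # 5 x MAD) but both samples adjacent to it are flagged by the jump rule
  s2 <- base
  s2$fwhm_hz[51:n] <- s2$fwhm_hz[51:n] + 0.7
  c2 <- clean_series(s2)
  expect_false(c2$valid[50])
  expect_false(c2$valid[51])
  expect_equal(sum(!c2$valid), 2L)
})

test_that("the BOLD regressor matches a brute-force convolution oracle", {
  p <- mini_params()
  sched <- build_schedule(p, mini_design(), seed = 1)
  hrf <- hrf_params()
  reg <- build_bold_regressor(sched, hrf)
  # oracle: fine-grid discrete convolution of the impulse train,
  # via power-of-two zero-padded FFTs
  dt <- 0.001
  tmax <- max(sched$onset_s) + 1
  grid <- seq(0, tmax, by = dt)
  imp <- numeric(length(grid))
  imp[pmin(length(grid), round(trial_onsets_s(sched) / dt) + 1L)] <- 1
  kern <- hrf_kernel(seq(0, hrf$length_s, by = dt), hrf)
  L <- 2^ceiling(log2(length(grid) + length(kern)))
  conv <- Re(fft(fft(c(imp, rep(0, L - length(imp)))) *
                   fft(c(kern, rep(0, L - length(kern)))),
                 inverse = TRUE))[seq_along(grid)] / L
  at <- sched$onset_s[sched$is_wref]
  oracle <- conv[round(at / dt) + 1L]
  oracle <- oracle / max(oracle)
  expect_equal(reg, oracle, tolerance = 1e-3)
  expect_equal(max(reg), 1)
})

test_that("single-event regressor peaks near onset + peak delay", {
  p <- mini_params()
  sched <- build_schedule(p, mini_design(), seed = 1)
  ev <- 30
  at <- sched$onset_s[sched$is_wref]
  r <- hrf_kernel(at - ev)
  expect_equal(at[which.max(r)], at[which.min(abs(at - (ev + 6)))])
  expect_error(build_bold_regressor(
    build_schedule(mini_params(),
                   task_design(n_on_blocks = 0L, initial_off_s = 240),
                   seed = 1)), "no trial")
  # block of events superposes above the single-event peak
  blk <- hrf_response(seq(0, 120, 0.5), seq(30, 60, 1.5))
  expect_gt(max(blk), max(hrf_kernel(seq(0, 32, 0.01))))
})

test_that("noiseless simulated narrowing of 0.5 Hz is recovered to 0.01", {
  p <- mini_params()
  sched <- build_schedule(p, mini_design(), seed = 1)
  ser <- simulate_transients(sched, quiet_truth(bold_narrowing_hz = 0.5),
                             p, seed = 2)
  lw <- clean_series(fit_linewidth_series(ser))
  est <- estimate_bold(lw, build_bold_regressor(sched))
  expect_equal(est$delta_fwhm_hz, 0.5, tolerance = 0.01 / 0.5)
  expect_true(est$reliable)
})

test_that("null and drift-only series give a null BOLD estimate", {
  p <- mini_params()
  sched <- build_schedule(p, mini_design(), seed = 1)
  tr <- subject_truth(bold_narrowing_hz = 0, noise_sd = 0.5)
  ser <- simulate_transients(sched, tr, p, seed = 3)
  lw <- clean_series(fit_linewidth_series(ser))
  # a well-behaved noisy series loses at most a small fraction of samples
  expect_lte(attr(lw, "n_invalidated") / nrow(lw), 0.2)
  est <- estimate_bold(lw, build_bold_regressor(sched))
  expect_lt(abs(est$delta_fwhm_hz), 3 * est$se)
  # pure linear trend in linewidth: drift covariate absorbs it
  lw2 <- lw
  lw2$fwhm_hz <- 8 + 0.001 * lw2$onset_s
  est2 <- estimate_bold(lw2, build_bold_regressor(sched))
  expect_lt(abs(est2$delta_fwhm_hz), 1e-8)
})

test_that("rank-deficient BOLD designs raise an error naming columns", {
  base <- data.frame(index = 1:30, onset_s = (1:30) * 4.5,
                     fwhm_hz = rnorm(30, 8, 0.05), eta = 1,
                     amplitude = 100, area = 1000, valid = TRUE)
  class(base) <- c("linewidth_series", "data.frame")
  reg <- rep(0.5, 30)   # constant regressor, collinear with intercept
  expect_error(estimate_bold(base, reg), "collinear")
})
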