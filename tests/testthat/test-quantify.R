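make_diff_spectrum <- function(p = test_params(), amp_gaba = 2.5,
                               amp_glx = 15, amp_naa = 30, fwhm = 8,
                               noise_sd = 0, seed = 1) {
  t_s <- (seq_len(p$n_points) - 1L) / p$spectral_width_hz
  comp <- function(shape, a, ppm, w) {
    env <- if (shape == "l") exp(-pi * w * t_s) else
      exp(-(pi * w * t_s)^2 / (4 * log(2)))
    a * env * exp(2i * pi * (ppm - p$water_ppm) * p$f0_mhz * t_s)
  }
  fid <- comp("g", amp_gaba, 3.01, fwhm) +
    comp("g", amp_glx / 2, 3.71, fwhm) + comp("g", amp_glx / 2, 3.79, fwhm) -
    comp("l", 0.5 * amp_naa, 2.01, fwhm)
  sp <- fid_to_spectrum(fid, p)
  if (noise_sd > 0) {
    set.seed(seed)
    sp$values <- sp$values +
      complex(real = rnorm(p$n_points, 0, noise_sd),
              imaginary = rnorm(p$n_points, 0, noise_sd))
  }
  sp
}

test_that("difference-spectrum fit recovers known areas within 1%", {
  p <- test_params()
  sp <- make_diff_spectrum(p)
  fit <- fit_diff(sp)
  expect_true(all(fit$converged))
  # discrete area scale: amplitude * bandwidth / 2
  a_scale <- p$spectral_width_hz / 2
  expect_equal(fit$area[fit$name == "glx"], 15 * a_scale, tolerance = 0.01)
  expect_equal(fit$area[fit$name == "gaba"], 2.5 * a_scale,
               tolerance = 0.01)
  expect_equal(fit$area[fit$name == "naa"], -15 * a_scale,
               tolerance = 0.01)
  expect_equal(fit$fwhm_hz, rep(8, 3), tolerance = 0.005)
  expect_lt(abs(fit$center_ppm[fit$name == "gaba"] - 3.01), 0.005)
})

test_that("a pure Gaussian's fitted FWHM matches 2*sqrt(2 ln 2) * sigma", {
  p <- test_params()
  sigma_hz <- 4
  fwhm_true <- 2 * sqrt(2 * log(2)) * sigma_hz
  sp <- peak_spectrum("gauss", fwhm_hz = fwhm_true, amp = 3, ppm = 3.01,
                      params = p)
  fit <- fit_diff(sp)
  g <- fit[fit$name == "gaba", ]
  expect_true(g$converged)
  expect_equal(g$fwhm_hz, fwhm_true, tolerance = 0.005)
})

test_that("an all-zero spectrum yields a non-convergence flag, not an error", {
  p <- test_params()
  sp <- mrs_spectrum(rep(0 + 0i, p$n_points),
                     seq(10, 0, length.out = p$n_points), p$f0_mhz)
  fit <- fit_diff(sp)
  expect_false(any(fit$converged))
  expect_true(all(is.na(fit$area)))
})

test_that("edit-OFF fit recovers the Cr/NAA area ratio within 1%", {
  p <- test_params()
  t_s <- (seq_len(p$n_points) - 1L) / p$spectral_width_hz
  line <- function(a, ppm) a * exp(-pi * 8 * t_s) *
    exp(2i * pi * (ppm - p$water_ppm) * p$f0_mhz * t_s)
  sp <- fid_to_spectrum(line(30, 2.01) + line(20, 3.03) + line(6, 3.20), p)
  fit <- fit_editoff(sp)
  expect_true(all(fit$converged))
  ratio <- fit$area[fit$name == "cr"] / fit$area[fit$name == "naa"]
  expect_equal(ratio, 20 / 30, tolerance = 0.01)
  # amplitude-zero Cho: area consistent with zero
  sp0 <- fid_to_spectrum(line(30, 2.01) + line(20, 3.03), p)
  fit0 <- fit_editoff(sp0)
  expect_lt(abs(fit0$area[fit0$name == "cho"]),
            3 * max(fit0$residual_sd[1], 1e-6) * 8 * pi)
  # baseline-only input: every area consistent with zero
  base <- mrs_spectrum(rep(2 + 0i, p$n_points),
                       seq(12, 0, length.out = p$n_points), p$f0_mhz)
  fitb <- fit_editoff(base)
  if (any(fitb$converged)) expect_true(all(abs(fitb$area) < 1))
})

test_that("QC stages fire at the documented thresholds, in order", {
  p <- test_params()
  sp <- make_diff_spectrum(p, noise_sd = 0.5)
  fake_fit <- function(gaba_fwhm, naa_fwhm, naa_amp) {
    f <- fit_diff(sp)
    f$fwhm_hz[f$name == "gaba"] <- gaba_fwhm
    f$fwhm_hz[f$name == "naa"] <- naa_fwhm
    f$amplitude[f$name == "naa"] <- naa_amp
    f
  }
  noise <- sd(Re(sp$values[sp$ppm_axis >= 9.5 & sp$ppm_axis <= 10.5]))
  expect_equal(compute_qc(fake_fit(31, 8, 1e6), sp)$reject_stage,
               "linewidth")
  expect_equal(compute_qc(fake_fit(29, 12.5, 1e6), sp)$reject_stage,
               "linewidth")
  # passes linewidth, SNR 19 -> snr stage
  expect_equal(compute_qc(fake_fit(29, 11, 19 * 2 * noise), sp)$reject_stage,
               "snr")
  # SNR exactly 20 passes ("below 20" is strict)
  expect_equal(compute_qc(fake_fit(29, 11, 20 * 2 * noise), sp)$reject_stage,
               "none")
})

test_that("MAD outlier rejection matches hand-enumerated cases", {
  d <- data.frame(gaba_iu = c(10, 11, 12, 13, 50), glx_iu = 15,
                  reject_stage = "none", usable = TRUE)
  out <- reject_outliers(d)
  expect_equal(out$reject_stage, c(rep("none", 4), "outlier"))
  expect_equal(out$usable, c(rep(TRUE, 4), FALSE))
  d2 <- data.frame(gaba_iu = c(10, 11, 12, 13, 16), glx_iu = 15,
                   reject_stage = "none")
  expect_true(all(reject_outliers(d2)$reject_stage == "none"))
  d3 <- data.frame(gaba_iu = rep(7, 6), glx_iu = rep(3, 6),
                   reject_stage = "none")
  expect_true(all(reject_outliers(d3)$reject_stage == "none"))
})

test_that("the serial three-stage filter matches a brute-force oracle", {
  # independent oracle: literal three-pass re-implementation
  oracle <- function(d) {
    stage <- rep("none", nrow(d))
    stage[d$gaba_fwhm_hz > 30 | d$naa_fwhm_hz > 12] <- "linewidth"
    stage[stage == "none" & d$naa_snr < 20] <- "snr"
    surv <- which(stage == "none")
    for (col in c("gaba_iu", "glx_iu")) {
      x <- d[[col]][surv]
      med <- median(x)
      mad_raw <- median(abs(x - med))
      if (mad_raw > 0)
        stage[surv][abs(x - med) > 5 * mad_raw] <- "outlier"
    }
    stage
  }
  apply_serial <- function(d) {
    stage <- rep("none", nrow(d))
    for (i in seq_len(nrow(d))) {
      q <- data.frame(gaba_fwhm_hz = d$gaba_fwhm_hz[i],
                      naa_fwhm_hz = d$naa_fwhm_hz[i],
                      naa_snr = d$naa_snr[i], reject_stage = "none")
      if (q$gaba_fwhm_hz > 30 || q$naa_fwhm_hz > 12) stage[i] <- "linewidth"
      else if (q$naa_snr < 20) stage[i] <- "snr"
    }
    d$reject_stage <- stage
    reject_outliers(d)$reject_stage
  }
  set.seed(11)
  for (rep in 1:5) {
    n <- 200L
    d <- data.frame(
      gaba_fwhm_hz = c(sample(c(10, 25, 30, 31, 35), n, TRUE)),
      naa_fwhm_hz = sample(c(6, 11, 12, 12.5), n, TRUE),
      naa_snr = sample(c(5, 19, 20, 21, 150), n, TRUE),
      gaba_iu = round(rnorm(n, 2.5, 0.4) + rbinom(n, 1, 0.05) * 8, 2),
      glx_iu = round(rnorm(n, 15, 1.5) + rbinom(n, 1, 0.05) * 30, 2))
    expect_identical(apply_serial(d), oracle(d))
  }
  # order dependence: shuffling stages changes the outcome on a crafted set
  crafted <- data.frame(
    gaba_fwhm_hz = c(10, 10, 10, 10, 35), naa_fwhm_hz = 8,
    naa_snr = c(100, 100, 100, 100, 100),
    gaba_iu = c(2, 2.1, 2.2, 2.3, 9), glx_iu = 15)
  serial <- apply_serial(crafted)
  # MAD-first (wrong order) oracle: outlier screen sees the linewidth-bad row
  mad_first <- {
    stage <- rep("none", 5)
    x <- crafted$gaba_iu
    med <- median(x)
    madr <- median(abs(x - med))
    if (madr > 0) stage[abs(x - med) > 5 * madr] <- "outlier"
    stage[stage == "none" & crafted$gaba_fwhm_hz > 30] <- "linewidth"
    stage
  }
  expect_false(identical(serial, mad_first))
})

test_that("water scaling is linear and guards its inputs", {
  p <- test_params()
  fit <- fit_diff(make_diff_spectrum(p))
  s1 <- scale_to_iu(fit, water_area = 1000)
  s2 <- scale_to_iu(fit, water_area = 500)
  expect_equal(s2$iu, 2 * s1$iu)
  fit0 <- fit
  fit0$area <- 0
  expect_equal(scale_to_iu(fit0, 1000)$iu, rep(0, 3))
  expect_error(scale_to_iu(fit, 0), "positive")
  expect_error(scale_to_iu(fit, -3), "positive")
})

test_that("increasing noise never decreases the fitted residual SD", {
  p <- test_params()
  sds <- c(0.1, 0.3, 0.6, 1, 2, 4)
  res <- sapply(seq_along(sds), function(i) {
    f <- fit_diff(make_diff_spectrum(p, noise_sd = sds[i], seed = 20 + i))
    f$residual_sd[f$name == "glx"]
  })
  expect_gt(cor(sds, res, method = "spearman"), 0.9)
})
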