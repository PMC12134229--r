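test_that("temporal bin edges are lower-inclusive and outer bins open", {
  expect_equal(assign_bin(0.150), 1L)
  expect_equal(assign_bin(0.183), 2L)   # lower limit inclusive
  expect_equal(assign_bin(0.090), 0L)
  expect_equal(assign_bin(0.350), 4L)
  expect_equal(assign_bin(c(0.100, 0.267, 0.2669, 0.5)), c(1L, 3L, 2L, 4L))
  expect_error(assign_bin(-0.1), "non-negative")
})

test_that("with no nuisance variance the GLM reduces to per-condition means", {
  p <- mini_params()
  sched <- build_schedule(p, mini_design(), seed = 1)
  ser <- simulate_transients(sched, quiet_truth(task_glx_frac = 0.06), p,
                             seed = 2)
  cs <- fit_condition_glm(ser, reg = NULL, use_nuisance = FALSE)
  # oracle: plain means per condition and edit state
  rows <- which(!sched$is_wref & sched$task_state == "OFF" &
                  sched$edit_state == "ON")
  mean_on <- colMeans(t(apply(ser$fids[rows, ], 1, function(f)
    fid_to_spectrum(f, p)$values)))
  rows_off <- which(!sched$is_wref & sched$task_state == "OFF" &
                      sched$edit_state == "OFF")
  mean_off <- colMeans(t(apply(ser$fids[rows_off, ], 1, function(f)
    fid_to_spectrum(f, p)$values)))
  expect_equal(cs$diff_off_task$values, mean_on - mean_off,
               tolerance = 1e-9)
})

test_that("DIFF of identical edit states is zero and signs are correct", {
  p <- mini_params()
  sched <- build_schedule(p, mini_design(), seed = 1)
  ser <- simulate_transients(sched, quiet_truth(), p, seed = 2)
  # force edit-ON content identical to edit-OFF: DIFF must vanish
  # (task fractions zeroed so every metabolite transient is identical)
  ser2 <- simulate_transients(sched, quiet_truth(task_glx_frac = 0,
                                                 task_gaba_frac = 0),
                              p, seed = 2)
  met <- which(!sched$is_wref)
  on <- met[sched$edit_state[met] == "ON"]
  off <- met[sched$edit_state[met] == "OFF"]
  for (k in seq_along(on)) ser2$fids[on[k], ] <- ser2$fids[off[min(k, length(off))], ]
  cs0 <- fit_condition_glm(ser2, reg = NULL, use_nuisance = FALSE)
  expect_lt(max(Mod(cs0$diff_off_task$values)), 1e-8 * max(Mod(ser$fids)))
  # true simulation: GABA+ positive at 3.0 ppm, NAA negative at 2.0 ppm
  cs <- fit_condition_glm(ser, reg = NULL, use_nuisance = FALSE)
  d <- cs$diff_off_task
  sel_gaba <- d$ppm_axis > 2.9 & d$ppm_axis < 3.1
  sel_naa <- d$ppm_axis > 1.9 & d$ppm_axis < 2.1
  expect_gt(sum(Re(d$values[sel_gaba])), 0)
  expect_lt(sum(Re(d$values[sel_naa])), 0)
})

test_that("phase-cycle-locked artefact is removed by the nuisance column", {
  p <- mini_params()
  sched <- build_schedule(p, mini_design(), seed = 1)
  ser <- simulate_transients(sched, quiet_truth(pc_offset = 2), p, seed = 2)
  clean <- simulate_transients(sched, quiet_truth(pc_offset = 0), p,
                               seed = 2)
  cs_clean <- fit_condition_glm(clean, reg = NULL, use_nuisance = FALSE)
  cs_no <- fit_condition_glm(ser, reg = NULL, use_nuisance = FALSE)
  cs_pc <- fit_condition_glm(ser, reg = NULL, use_nuisance = TRUE)
  dev <- function(cs) max(Mod(cs$editoff_off_task$values -
                                cs_clean$editoff_off_task$values))
  expect_gt(dev(cs_no), 100)        # sign-locked artefact leaks through
  expect_lt(dev(cs_pc), 1e-6)       # regressor absorbs it exactly
})

test_that("motion regressors reduce spike-induced Glx bias", {
  p <- mini_params()
  sched <- build_schedule(p, mini_design(), seed = 1)
  tr <- subject_truth(noise_sd = 0.2, motion_spike_prob = 0.08,
                      task_glx_frac = 0)
  ser <- simulate_transients(sched, tr, p, seed = 6)
  reg <- register_spectra(ser)
  cs_with <- fit_condition_glm(reg$series, reg$estimates)
  cs_without <- fit_condition_glm(reg$series, reg$estimates,
                                  use_nuisance = FALSE)
  truth_area <- 15000   # amp_glx 15, discrete area scale (amp * sw / 2)
  glx_area <- function(cs) {
    f <- fit_diff(cs$diff_off_task)
    f$area[f$name == "glx"]
  }
  expect_lte(abs(glx_area(cs_with) - truth_area),
             abs(glx_area(cs_without) - truth_area) + 20)
})

test_that("empty bins are flagged absent, not zero", {
  p <- mini_params()
  # jitter restricted to the middle bin: bins 0, 1, 3, 4 stay empty
  d <- task_design(n_on_blocks = 2L, jitter_range_s = c(0.190, 0.260))
  sched <- build_schedule(p, d, seed = 1)
  ser <- simulate_transients(sched, quiet_truth(), p, seed = 2)
  cs <- fit_condition_glm(ser, reg = NULL, use_nuisance = FALSE)
  expect_null(cs$diff_bins[[1]])
  expect_null(cs$diff_bins[[2]])
  expect_s3_class(cs$diff_bins[[3]], "mrs_spectrum")
  expect_null(cs$diff_bins[[4]])
  expect_null(cs$diff_bins[[5]])
})

test_that("rank-deficient condition designs raise an error naming columns", {
  p <- mini_params()
  sched <- build_schedule(p, mini_design(), seed = 1)
  ser <- simulate_transients(sched, quiet_truth(), p, seed = 2)
  reg <- register_spectra(ser)
  # a constant phase-cycle column lies in the span of the cell-mean
  # condition indicators, so the design loses rank
  ser2 <- reg$series
  ser2$schedule$phase_step <- 0L
  expect_error(fit_condition_glm(ser2, reg$estimates), "collinear")
})

test_that("custom trial-condition labels produce per-condition DIFF spectra", {
  p <- mini_params()
  sched <- build_schedule(p, mini_design(), seed = 1)
  ser <- simulate_transients(sched, quiet_truth(task_glx_frac = 0), p,
                             seed = 2)
  labels <- ifelse(sched$task_state == "OFF", "task_off",
                   ifelse(sched$trial_id %% 2 == 0, "congruent",
                          "incongruent_correct"))
  cs <- fit_condition_glm(ser, reg = NULL, use_nuisance = FALSE,
                          labels = labels)
  expect_setequal(names(cs$diff_custom),
                  c("task_off", "congruent", "incongruent_correct"))
  # identical generating content in every condition: spectra agree
  expect_equal(cs$diff_custom$congruent$values,
               cs$diff_custom$incongruent_correct$values, tolerance = 1e-9)
  cs_std <- fit_condition_glm(ser, reg = NULL, use_nuisance = FALSE)
  expect_equal(cs$diff_off_task$values, cs_std$diff_off_task$values,
               tolerance = 1e-9)
})
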