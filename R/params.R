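#' Acquisition parameters for an interleaved GABA-edited fMRS sequence
#'
#' Bundles the sequence timing and sampling constants of the interleaved
#' MEGA-PRESS acquisition: spectral editing alternates between edit-ON
#' (editing pulse at 1.9 ppm) and edit-OFF (7.46 ppm) transients, and water
#' suppression is periodically disabled so that every `wref_every`-th
#' transient carries an unsuppressed water reference.
#'
#' @param te_s Echo time in seconds.
#' @param tr_s Repetition time in seconds.
#' @param edit_on_ppm Editing pulse centre frequency for edit-ON transients
#'   (ppm).
#' @param edit_off_ppm Editing pulse centre frequency for edit-OFF transients
#'   (ppm).
#' @param n_transients Total number of transients acquired.
#' @param wref_every Interleave period of the water-unsuppressed reference:
#'   every `wref_every`-th transient, at 0-based indices
#'   `wref_every - 1, 2 * wref_every - 1, ...` (see [build_schedule()]).
#' @param phase_cycle_steps Number of steps in the receiver phase cycle.
#' @param n_points Complex samples per FID.
#' @param spectral_width_hz Acquisition bandwidth in Hz.
#' @param f0_mhz Transmitter (Larmor) frequency in MHz; 127.7 for proton at
#'   3 T.
#' @param water_ppm Chemical shift of the water resonance / carrier (ppm).
#'
#' @return An object of class `acq_params` (a validated list).
#' @export
#' @examples
#' p <- acq_params()
#' p$tr_s
acq_params <- function(te_s = 0.068, tr_s = 1.5,
                       edit_on_ppm = 1.9, edit_off_ppm = 7.46,
                       n_transients = 700L, wref_every = 3L,
                       phase_cycle_steps = 2L,
                       n_points = 2048L, spectral_width_hz = 2000,
                       f0_mhz = 127.7, water_ppm = 4.68) {
  p <- list(te_s = te_s, tr_s = tr_s,
            edit_on_ppm = edit_on_ppm, edit_off_ppm = edit_off_ppm,
            n_transients = as.integer(n_transients),
            wref_every = as.integer(wref_every),
            phase_cycle_steps = as.integer(phase_cycle_steps),
            n_points = as.integer(n_points),
            spectral_width_hz = spectral_width_hz,
            f0_mhz = f0_mhz, water_ppm = water_ppm)
  class(p) <- "acq_params"
  validate_acq_params(p)
  p
}

validate_acq_params <- function(p) {
  stopifnot(inherits(p, "acq_params"))
  if (p$n_transients <= 0L)
    stop("n_transients must be positive", call. = FALSE)
  if (p$wref_every < 2L)
    stop("wref_every must be >= 2", call. = FALSE)
  if (p$spectral_width_hz / p$n_points >= 2)
    stop("spectral resolution too coarse: spectral_width_hz / n_points must be < 2 Hz",
         call. = FALSE)
  ppm <- c(p$edit_on_ppm, p$edit_off_ppm, p$water_ppm)
  if (any(ppm < 0 | ppm > 10))
    stop("ppm values must lie within [0, 10]", call. = FALSE)
  invisible(p)
}

#' Block-event task design for the Eriksen flanker paradigm
#'
#' Describes the task schedule used during acquisition: an initial task-OFF
#' block, then alternating task-ON / task-OFF blocks. Within each task-ON
#' block one flanker trial is presented per repetition time, with onset
#' jittered so that the stimulus precedes the excitation pulse by a
#' stimulus-to-acquisition interval drawn uniformly from `jitter_range_s`.
#'
#' @param initial_off_s Duration of the leading task-OFF block (s).
#' @param on_block_s Duration of each task-ON block (s).
#' @param off_block_s Duration of each subsequent task-OFF block (s).
#' @param n_on_blocks Number of task-ON blocks (11 for the fMRS session,
#'   6 for the fMRI session).
#' @param isi_s Inter-stimulus interval (s); equal to the repetition time.
#' @param p_incongruent Fraction of incongruent trials.
#' @param stim_duration_s Stimulus presentation duration (s).
#' @param response_window_s Nominal response window (s).
#' @param jitter_range_s Length-2 numeric: closed range of the
#'   stimulus-to-acquisition interval in seconds.
#'
#' @return An object of class `task_design`.
#' @export
#' @examples
#' d <- task_design()              # fMRS session: 11 task-ON blocks
#' design_duration_s(d)            # 1050 s
#' d2 <- task_design(n_on_blocks = 6L)  # fMRI session: 600 s
task_design <- function(initial_off_s = 60, on_block_s = 30, off_block_s = 60,
                        n_on_blocks = 11L, isi_s = 1.5,
                        p_incongruent = 0.4, stim_duration_s = 0.35,
                        response_window_s = 0.8,
                        jitter_range_s = c(0.100, 0.350)) {
  d <- list(initial_off_s = initial_off_s, on_block_s = on_block_s,
            off_block_s = off_block_s, n_on_blocks = as.integer(n_on_blocks),
            isi_s = isi_s, p_incongruent = p_incongruent,
            stim_duration_s = stim_duration_s,
            response_window_s = response_window_s,
            jitter_range_s = jitter_range_s)
  class(d) <- "task_design"
  validate_task_design(d)
  d
}

validate_task_design <- function(d) {
  stopifnot(inherits(d, "task_design"))
  if (d$p_incongruent < 0 || d$p_incongruent > 1)
    stop("p_incongruent must lie in [0, 1]", call. = FALSE)
  if (length(d$jitter_range_s) != 2L || d$jitter_range_s[1] >= d$jitter_range_s[2])
    stop("jitter_range_s must be an increasing length-2 range", call. = FALSE)
  blocks <- c(d$initial_off_s, d$on_block_s, d$off_block_s)
  if (any(abs(blocks / d$isi_s - round(blocks / d$isi_s)) > 1e-9))
    stop("block durations must be integer multiples of isi_s", call. = FALSE)
  invisible(d)
}

#' Total duration of a task design, in seconds
#'
#' @param design A [task_design()].
#' @return Total paradigm duration in seconds.
#' @export
design_duration_s <- function(design) {
  validate_task_design(design)
  design$initial_off_s +
    design$n_on_blocks * (design$on_block_s + design$off_block_s)
}

#' Number of trials in a task design
#'
#' One trial per inter-stimulus interval within each task-ON block.
#'
#' @param design A [task_design()].
#' @return Integer trial count.
#' @export
design_n_trials <- function(design) {
  validate_task_design(design)
  as.integer(round(design$n_on_blocks * design$on_block_s / design$isi_s))
}

#' Spectroscopy voxel volume in millilitres
#'
#' @param dims_mm Numeric length-3 vector of voxel edge lengths in mm.
#' @return Volume in mL.
#' @export
#' @examples
#' voxel_volume_ml(c(22, 36, 23))  # ACC voxel, 18.2 mL
voxel_volume_ml <- function(dims_mm) {
  stopifnot(length(dims_mm) == 3L, all(dims_mm > 0))
  prod(dims_mm) / 1000
}
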