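#' Build a per-transient acquisition schedule
#'
#' Lays the block-event task design over the interleaved MEGA-PRESS
#' acquisition, producing one record per transient with its timing, edit
#' state, water-reference flag, phase-cycle step, task state and (for
#' task-ON transients) the trial identifier and achieved
#' stimulus-to-acquisition interval `t_sa_s`.
#'
#' Conventions:
#' \itemize{
#'   \item The excitation pulse of transient \eqn{i} fires at
#'     `onset_s = i * tr_s` (0-based indices).
#'   \item Water-unsuppressed reference transients sit at 0-based indices
#'     `wref_every - 1, 2 * wref_every - 1, ...` (2, 5, 8, ... for the
#'     default every-third interleave); over 700 transients this gives 233
#'     water and 467 metabolite transients.
#'   \item The edit state alternates ON/OFF across \emph{metabolite}
#'     transients; a water-reference transient carries the edit state of the
#'     next metabolite transient without advancing the alternation.
#'   \item Every transient whose excitation falls inside a task-ON block has
#'     one flanker trial, presented `t_sa_s` seconds before the excitation,
#'     with `t_sa_s` drawn uniformly from `design$jitter_range_s`.
#' }
#'
#' @param params An [acq_params()] object.
#' @param design A [task_design()] object.
#' @param seed Integer seed for the stimulus-timing jitter.
#'
#' @return A `data.frame` of class `acq_schedule` with columns
#'   `index` (0-based), `onset_s`, `edit_state` ("ON"/"OFF"), `is_wref`,
#'   `phase_step` (0/1), `task_state` ("ON"/"OFF"), `block_id`, `trial_id`
#'   (NA for task-OFF) and `t_sa_s` (NA for task-OFF).
#' @export
#' @examples
#' sched <- build_schedule(acq_params(), task_design(), seed = 1)
#' nrow(sched)                       # 700
#' sum(sched$task_state == "ON")     # 220
build_schedule <- function(params, design, seed = 1L) {
  validate_acq_params(params)
  validate_task_design(design)

  n <- params$n_transients
  tr <- params$tr_s
  needed <- design_duration_s(design) / tr
  if (needed > n + 1e-9) {
    stop(sprintf(paste0("task design needs %d transients (design duration ",
                        "%g s / tr_s %g s) but params$n_transients is %d"),
                 as.integer(round(needed)), design_duration_s(design), tr, n),
         call. = FALSE)
  }

  idx <- seq_len(n) - 1L
  onset <- idx * tr
  is_wref <- (idx %% params$wref_every) == (params$wref_every - 1L)
  phase_step <- idx %% params$phase_cycle_steps

  # edit alternation over metabolite transients; wref inherits upcoming state
  edit_state <- character(n)
  state <- "ON"
  for (i in seq_len(n)) {
    edit_state[i] <- state
    if (!is_wref[i]) state <- if (state == "ON") "OFF" else "ON"
  }

  # block boundaries: initial OFF, then alternating ON / OFF
  block_start <- c(0, cumsum(c(design$initial_off_s,
                               rep(c(design$on_block_s, design$off_block_s),
                                   design$n_on_blocks))))
  block_start <- block_start[-length(block_start)]
  block_is_on <- c(FALSE, rep(c(TRUE, FALSE), design$n_on_blocks))
  block_id <- findInterval(onset + 1e-9, block_start) - 1L
  block_id[block_id >= length(block_start)] <- length(block_start) - 1L
  task_on <- block_is_on[block_id + 1L]

  trial_id <- rep(NA_integer_, n)
  t_sa <- rep(NA_real_, n)
  on_idx <- which(task_on)
  if (length(on_idx)) {
    trial_id[on_idx] <- seq_along(on_idx) - 1L
    t_sa[on_idx] <- with_seed(seed, stats::runif(
      length(on_idx), design$jitter_range_s[1], design$jitter_range_s[2]))
  }

  sched <- data.frame(index = idx, onset_s = onset,
                      edit_state = edit_state, is_wref = is_wref,
                      phase_step = phase_step,
                      task_state = ifelse(task_on, "ON", "OFF"),
                      block_id = block_id, trial_id = trial_id,
                      t_sa_s = t_sa, stringsAsFactors = FALSE)
  class(sched) <- c("acq_schedule", "data.frame")
  attr(sched, "params") <- params
  attr(sched, "design") <- design
  sched
}

#' Trial (stimulus) onset times of a schedule, in seconds
#'
#' @param schedule An `acq_schedule`.
#' @return Numeric vector of stimulus onsets, one per trial, ordered by
#'   trial id.
#' @export
trial_onsets_s <- function(schedule) {
  on <- schedule[!is.na(schedule$trial_id), , drop = FALSE]
  on <- on[order(on$trial_id), , drop = FALSE]
  on$onset_s - on$t_sa_s
}
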