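#' Simulate flanker-task behaviour for one subject
#'
#' Reaction times are drawn from a right-skewed (log-normal) distribution
#' with an additive congruency penalty; draws exceeding the response window
#' are recorded as omissions (no response, incorrect). Response accuracy is
#' Bernoulli with a lower rate for incongruent trials; the per-subject
#' rates come from `truth$behav`, with defaults depending on `truth$group`
#' (patients less accurate than controls).
#'
#' Exactly `round(p_incongruent * n)` trials are incongruent, assigned at
#' random positions.
#'
#' @param design A [task_design()].
#' @param truth A [subject_truth()]; `truth$behav` may override any of
#'   `acc_congruent`, `acc_incongruent`, `rt_median_s`,
#'   `rt_congruency_penalty_s`, `rt_sdlog`.
#' @param seed Integer seed.
#' @param session `"fMRS"` or `"fMRI"` (recorded in the log).
#' @return A `data.frame` trial log: `trial_id` (0-based), `congruent`,
#'   `rt_s` (NA for omissions), `correct`, `session`.
#' @export
simulate_behaviour <- function(design, truth, seed = 1L, session = "fMRS") {
  validate_task_design(design)
  b <- utils::modifyList(default_behav(truth$group), truth$behav)
  n <- design_n_trials(design)
  with_seed(seed, {
    n_inc <- as.integer(round(design$p_incongruent * n))
    congruent <- rep(TRUE, n)
    congruent[sample.int(n, n_inc)] <- FALSE
    med <- ifelse(congruent, b$rt_median_s,
                  b$rt_median_s + b$rt_congruency_penalty_s)
    rt <- stats::rlnorm(n, meanlog = log(med), sdlog = b$rt_sdlog)
    acc_p <- ifelse(congruent, b$acc_congruent, b$acc_incongruent)
    correct <- stats::runif(n) < acc_p
    omitted <- rt > design$response_window_s
    correct[omitted] <- FALSE
    rt[omitted] <- NA_real_
    data.frame(trial_id = seq_len(n) - 1L, congruent = congruent,
               rt_s = rt, correct = correct, session = session,
               stringsAsFactors = FALSE)
  })
}

default_behav <- function(group) {
  if (identical(group, "patient")) {
    list(acc_congruent = 0.90, acc_incongruent = 0.75,
         rt_median_s = 0.46, rt_congruency_penalty_s = 0.06,
         rt_sdlog = 0.22)
  } else {
    list(acc_congruent = 0.97, acc_incongruent = 0.88,
         rt_median_s = 0.44, rt_congruency_penalty_s = 0.06,
         rt_sdlog = 0.18)
  }
}
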