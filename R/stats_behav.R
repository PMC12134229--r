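#' Per-subject behavioural summary metrics
#'
#' Computes, overall and per congruency condition: response accuracy
#' (RA, correct / total), median reaction time over correct responses
#' (RT), their ratio RA/RT, and reaction-time slowing, defined as the
#' incongruent-minus-congruent difference of median correct RT.
#'
#' @param log A trial log from [simulate_behaviour()] (columns
#'   `congruent`, `rt_s`, `correct`).
#' @return A one-row data frame: `ra`, `rt_s`, `ra_over_rt`,
#'   `ra_congruent`, `ra_incongruent`, `rt_congruent_s`,
#'   `rt_incongruent_s`, `rt_slowing_s`, `n_trials`. RT-based metrics are
#'   `NA` (flagged) when a condition has no correct responses.
#' @export
behavioural_metrics <- function(log) {
  if (!nrow(log)) stop("empty trial log", call. = FALSE)
  med_rt <- function(sel) {
    r <- log$rt_s[sel & log$correct]
    if (!length(r) || all(is.na(r))) NA_real_ else
      stats::median(r, na.rm = TRUE)
  }
  ra <- mean(log$correct)
  rt <- med_rt(rep(TRUE, nrow(log)))
  rt_c <- med_rt(log$congruent)
  rt_i <- med_rt(!log$congruent)
  data.frame(
    ra = ra, rt_s = rt,
    ra_over_rt = if (is.na(rt)) NA_real_ else ra / rt,
    ra_congruent = mean(log$correct[log$congruent]),
    ra_incongruent = mean(log$correct[!log$congruent]),
    rt_congruent_s = rt_c, rt_incongruent_s = rt_i,
    rt_slowing_s = rt_i - rt_c,
    n_trials = nrow(log))
}

#' Nonparametric rank tests for related and unrelated samples
#'
#' Wilcoxon signed-rank for paired samples, Mann-Whitney U for unpaired,
#' both two-sided (exact where the implementation allows, normal
#' approximation otherwise). A degenerate paired comparison with all-tied
#' differences returns `p = 1` with a warning.
#'
#' @param a,b Numeric samples (equal length when `paired`).
#' @param paired Related samples?
#' @return A list: `statistic` (V for paired, U for unpaired), `p`,
#'   `method`.
#' @export
rank_tests <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  if (paired && all(a - b == 0)) {
    warning("all paired differences are ties; degenerate p = 1")
    return(list(statistic = 0, p = 1,
                method = "Wilcoxon signed rank (degenerate)"))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            exact = NULL, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value, method = ht$method)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down adjustment with monotonicity enforcement, capped at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and length.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.04 0.04
holm_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "holm")
}

#' Task-elicited metabolite change per subject
#'
#' `delta = task-ON estimate - task-OFF estimate` for Glx and GABA+, with
#' usability propagated: if either condition is unusable the delta is
#' absent (`NA`), never zero.
#'
#' @param estimates Long-format data frame with columns `subject_id`,
#'   `condition` (`"task_on"` / `"task_off"`), `glx_iu`, `gaba_iu`,
#'   `usable`.
#' @return One row per subject: `subject_id`, `delta_glx_iu`,
#'   `delta_gaba_iu`, `usable`.
#' @export
delta_metabolites <- function(estimates) {
  split_rows <- split(estimates, estimates$subject_id)
  out <- lapply(split_rows, function(d) {
    on <- d[d$condition == "task_on", ]
    off <- d[d$condition == "task_off", ]
    ok <- nrow(on) == 1L && nrow(off) == 1L && on$usable && off$usable
    data.frame(subject_id = d$subject_id[1],
               delta_glx_iu = if (ok) on$glx_iu - off$glx_iu else NA_real_,
               delta_gaba_iu = if (ok) on$gaba_iu - off$gaba_iu else NA_real_,
               usable = ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
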