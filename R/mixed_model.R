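#' Linear mixed-effects model of metabolite estimates with residual filter
#'
#' Random-intercept model of the long-format (subject x condition)
#' metabolite estimates:
#' `response ~ group * condition + fgm + age_y + (1 | subject_id)`,
#' where `condition` is the task state (`task_off` reference vs
#' `task_on`), the stimulus-and-accuracy condition, or the
#' stimulus-to-acquisition temporal bin, depending on `factors`. After an
#' initial fit, observations whose residual deviates from the median
#' residual by more than `mad_mult` times the normal-consistent MAD
#' (scale factor 1.4826, so the default 2.5 corresponds to about 3.7
#' residual SDs) are excluded and the model refitted once. The
#' consistency scaling keeps the screen aimed at genuinely strong
#' residuals: an unscaled cutoff of 2.5 raw MADs (about 1.7 SDs) would
#' trim healthy observations, shrink the residual variance and inflate
#' the type-I error of every term. P-values use the Satterthwaite
#' approximation (lmerTest); confidence intervals are Wald. A singular
#' random-effects fit falls back to ordinary least squares (random
#' intercept dropped) with a warning.
#'
#' The `fgm` and `age_y` covariates are mean-centred before fitting, so
#' the intercept is the reference-group task-OFF level at sample-average
#' grey-matter fraction and age; the reported percent task effect (task
#' coefficient over intercept) is therefore a fraction of a typical
#' baseline level rather than of an extrapolation to zero covariates.
#'
#' @param long_table Data frame with columns `subject_id`, `group`,
#'   `condition`, `fgm`, `age_y` and the response column; at least two
#'   observations per subject.
#' @param response `"glx"` or `"gaba"` (column `<response>_iu`).
#' @param factors Which condition factor the `condition` column encodes:
#'   `"task_state"`, `"stimulus_and_accuracy"` or `"time_bin"`.
#' @param mad_mult Residual-filter multiplier (default 2.5, applied to
#'   the normal-consistent MAD).
#' @return A `model_result` with `terms`, `n_used`, `dropped`,
#'   `percent_task_effect` (task coefficient over intercept, x100; only
#'   for `factors = "task_state"`), and the fitted model.
#' @export
fit_mixed_model <- function(long_table, response = c("glx", "gaba"),
                            factors = c("task_state",
                                        "stimulus_and_accuracy",
                                        "time_bin"),
                            mad_mult = 2.5) {
  response <- match.arg(response)
  factors <- match.arg(factors)
  resp_col <- paste0(response, "_iu")
  need <- c(resp_col, "subject_id", "group", "condition", "fgm", "age_y")
  miss <- setdiff(need, names(long_table))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- long_table[stats::complete.cases(long_table[, need]), , drop = FALSE]
  if (min(table(d$subject_id)) < 2L)
    warning("some subjects contribute fewer than 2 observations")
  d$group <- factor(d$group, levels = c("control", "patient"))
  d$fgm <- d$fgm - mean(d$fgm)
  d$age_y <- d$age_y - mean(d$age_y)
  ref <- switch(factors, task_state = "task_off",
                stimulus_and_accuracy = "congruent",
                time_bin = "task_off")
  lev <- unique(d$condition)
  d$condition <- factor(d$condition, levels = c(ref, setdiff(sort(lev), ref)))

  f <- stats::as.formula(
    sprintf("%s ~ group * condition + fgm + age_y + (1 | subject_id)",
            resp_col))
  fit_once <- function(dd) {
    suppressMessages(lmerTest::lmer(f, data = dd, REML = TRUE))
  }
  fit0 <- fit_once(d)

  # residual filter: normal-consistent MAD about the median residual
  r <- stats::resid(fit0)
  med <- stats::median(r)
  mad_c <- 1.4826 * stats::median(abs(r - med))
  keep <- if (mad_c == 0) rep(TRUE, length(r)) else
    abs(r - med) <= mad_mult * mad_c
  d2 <- d[keep, , drop = FALSE]
  fit <- fit_once(d2)

  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("singular random-intercept fit; falling back to OLS")
    f_ols <- stats::as.formula(
      sprintf("%s ~ group * condition + fgm + age_y", resp_col))
    fit <- stats::lm(f_ols, data = d2)
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)
  } else {
    sm <- stats::coef(summary(fit))
    colnames(sm)[colnames(sm) == "Pr(>|t|)"] <- "Pr(>|t|)"
    ci <- suppressMessages(
      stats::confint(fit, parm = "beta_", method = "Wald"))
  }
  terms <- data.frame(name = rownames(sm), estimate = sm[, "Estimate"],
                      ci95_lo = ci[rownames(sm), 1],
                      ci95_hi = ci[rownames(sm), 2],
                      p = sm[, "Pr(>|t|)"], row.names = NULL,
                      stringsAsFactors = FALSE)

  pct <- NA_real_
  if (factors == "task_state") {
    ic <- terms$estimate[terms$name == "(Intercept)"]
    tc <- terms$estimate[grepl("^conditiontask_on$", terms$name)]
    if (length(ic) && length(tc) && ic != 0) pct <- tc / ic * 100
  }
  structure(list(terms = terms, n_used = nrow(d2),
                 dropped = data.frame(
                   id = as.character(d$subject_id[!keep]),
                   reason = rep(sprintf("|resid - median| > %.1f x MAD",
                                        mad_mult), sum(!keep)),
                   stringsAsFactors = FALSE),
                 diagnostics = NULL, warnings = if (singular)
                   "singular random effects; OLS fallback" else character(0),
                 percent_task_effect = pct, model = fit,
                 formula = f),
            class = "model_result")
}
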