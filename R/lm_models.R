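# Influence-screened OLS with specification diagnostics, plus the
# medication model. Shared machinery: single-pass DFFITS screening at
# 2 * sqrt(k / n), then Jarque-Bera normality and White heteroscedasticity /
# specification checks on the final fit.

jarque_bera_p <- function(resid) {
  n <- length(resid)
  r <- resid - mean(resid)
  s2 <- mean(r^2)
  S <- mean(r^3) / s2^1.5
  K <- mean(r^4) / s2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  stats::pchisq(jb, df = 2, lower.tail = FALSE)
}

# auxiliary-regression LM tests of White: squared residuals on the model's
# regressors plus their squares (LM variant) or plus squares and pairwise
# cross products (two-moment specification variant); statistic n * R^2.
white_tests <- function(model) {
  X <- stats::model.matrix(model)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  e2 <- stats::resid(model)^2
  aux_p <- function(Z) {
    Z <- Z[, apply(Z, 2, function(v) stats::sd(v) > 0), drop = FALSE]
    Z <- qr.Q(qr(Z))[, seq_len(qr(Z)$rank), drop = FALSE]
    fit <- stats::lm(e2 ~ Z)
    r2 <- summary(fit)$r.squared
    stats::pchisq(length(e2) * r2, df = ncol(Z), lower.tail = FALSE)
  }
  sq <- X^2
  colnames(sq) <- paste0(colnames(X), "_sq")
  cross <- NULL
  if (ncol(X) > 1L) {
    cb <- utils::combn(ncol(X), 2)
    cross <- sapply(seq_len(ncol(cb)), function(j)
      X[, cb[1, j]] * X[, cb[2, j]])
    if (is.null(dim(cross))) cross <- matrix(cross, ncol = 1)
  }
  list(white_lm_p = aux_p(cbind(X, sq)),
       white_spec_p = aux_p(cbind(X, sq, cross)))
}

# fit, single-pass DFFITS screen, refit, diagnose
ols_screened <- function(formula, data, id_col = "subject_id",
                         dffits_mult = 2) {
  rownames(data) <- NULL
  fit0 <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit0)))) {
    bad <- names(stats::coef(fit0))[is.na(stats::coef(fit0))]
    stop("inestimable model terms (collinear): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  k <- length(stats::coef(fit0))
  n <- nrow(stats::model.frame(fit0))
  thr <- dffits_mult * sqrt(k / n)
  dff <- stats::dffits(fit0)
  drop_idx <- which(abs(dff) > thr)

  used <- stats::model.frame(fit0)
  keep_rows <- setdiff(seq_len(n), drop_idx)
  data_final <- data[as.integer(rownames(used))[keep_rows], , drop = FALSE]
  fit <- stats::lm(formula, data = data_final)

  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  terms <- data.frame(name = rownames(sm), estimate = sm[, "Estimate"],
                      ci95_lo = ci[, 1], ci95_hi = ci[, 2],
                      p = sm[, "Pr(>|t|)"], row.names = NULL,
                      stringsAsFactors = FALSE)
  wt <- white_tests(fit)
  diagnostics <- c(jarque_bera_p = jarque_bera_p(stats::resid(fit)),
                   white_lm_p = wt$white_lm_p,
                   white_spec_p = wt$white_spec_p)
  warn <- character(0)
  if (any(diagnostics < 0.05, na.rm = TRUE))
    warn <- paste("model-suitability: diagnostic p < 0.05 (",
                  paste(names(diagnostics)[diagnostics < 0.05],
                        collapse = ", "), ")")
  dropped_ids <- if (length(drop_idx)) {
    rows <- as.integer(rownames(used))[drop_idx]
    if (id_col %in% names(data)) data[[id_col]][rows] else rows
  } else character(0)

  structure(list(terms = terms, n_used = nrow(data_final),
                 dropped = data.frame(
                   id = as.character(dropped_ids),
                   reason = sprintf("|DFFITS| > %.3f", thr),
                   stringsAsFactors = FALSE),
                 diagnostics = diagnostics, warnings = warn,
                 dffits_threshold = thr, model = fit,
                 formula = stats::formula(fit)),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result> ", deparse(x$formula), "\n", sep = "")
  print(x$terms, digits = 3)
  cat(sprintf("n_used = %d, dropped = %d\n", x$n_used, nrow(x$dropped)))
  if (length(x$warnings)) cat("warning:", x$warnings, "\n")
  invisible(x)
}

#' Baseline metabolite model: group, BOLD and their interaction
#'
#' Least-squares model of the baseline (task-OFF) metabolite estimate on
#' group, the BOLD covariate, their interaction, grey-matter fraction and
#' age: `response ~ group * BOLD + fgm + age_y`. Observations with
#' `|DFFITS| > 2 * sqrt(k / n)` are dropped in a single pass and the model
#' refitted; Jarque-Bera and White diagnostics are evaluated on the final
#' fit and a `model-suitability` warning recorded (never silent) when any
#' has p < 0.05.
#'
#' @param table One row per subject with columns `group`
#'   (`control`/`patient`), the response (`glx_iu` or `gaba_iu`), the BOLD
#'   covariate (`bold_fmri_z` or `bold_fmrs`), `fgm` and `age_y`.
#' @param response `"glx"` or `"gaba"`.
#' @param bold_source `"fmri"` (median fMRI Z over the spectroscopy
#'   voxel) or `"fmrs"` (water-linewidth `delta_fwhm_hz`).
#' @return A `model_result`: `terms` (estimate, CI95, p per term),
#'   `n_used`, `dropped`, `diagnostics`, `warnings`.
#' @export
fit_baseline_model <- function(table, response = c("glx", "gaba"),
                               bold_source = c("fmri", "fmrs")) {
  response <- match.arg(response)
  bold_source <- match.arg(bold_source)
  resp_col <- paste0(response, "_iu")
  bold_col <- if (bold_source == "fmri") "bold_fmri_z" else "bold_fmrs"
  need <- c(resp_col, bold_col, "group", "fgm", "age_y")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- table[stats::complete.cases(table[, need]), , drop = FALSE]
  d$group <- factor(d$group, levels = c("control", "patient"))
  f <- stats::as.formula(sprintf("%s ~ group * %s + fgm + age_y",
                                 resp_col, bold_col))
  ols_screened(f, d)
}

#' Medication model: GABA+ against antipsychotic dose
#'
#' `gaba_iu ~ is_active * ddd + fgm + age_y + panss_pos` on patient rows,
#' with the same influence screening and diagnostics as
#' [fit_baseline_model()]. If `is_active` does not vary the interaction is
#' dropped with a warning; if `ddd` does not vary the dose term is
#' inestimable and an error naming the column is raised.
#'
#' @param table Subject table; only rows with `group == "patient"` and
#'   non-missing `ddd` are used.
#' @return A `model_result`.
#' @export
medication_model <- function(table) {
  d <- table[table$group == "patient" & !is.na(table$ddd), , drop = FALSE]
  need <- c("gaba_iu", "ddd", "is_active", "fgm", "age_y", "panss_pos")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- d[stats::complete.cases(d[, need]), , drop = FALSE]
  if (nrow(d) < 8L) stop("too few patient rows with ddd", call. = FALSE)
  if (stats::sd(d$ddd) == 0)
    stop("ddd does not vary; dose term inestimable (column: ddd)",
         call. = FALSE)
  if (length(unique(d$is_active)) < 2L) {
    warning("is_active is constant; interaction dropped")
    f <- gaba_iu ~ ddd + fgm + age_y + panss_pos
  } else {
    f <- gaba_iu ~ is_active * ddd + fgm + age_y + panss_pos
  }
  ols_screened(f, d)
}
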