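#' Assign a stimulus-to-acquisition interval to its temporal bin
#'
#' Five bins with edges at 100, 183, 267 and 350 ms, open at either end,
#' lower limits inclusive: bin 0 covers `t < 0.100` s, bin 1
#' `0.100 <= t < 0.183`, bin 2 `0.183 <= t < 0.267`, bin 3
#' `0.267 <= t < 0.350`, and bin 4 `t >= 0.350`. The inner three bins
#' evenly cover the nominal 100-350 ms jitter range.
#'
#' @param t_sa_s Stimulus-to-acquisition interval(s) in seconds, >= 0.
#' @return Integer bin index/indices in 0..4.
#' @export
#' @examples
#' assign_bin(c(0.090, 0.150, 0.183, 0.350))  # 0 1 2 4
assign_bin <- function(t_sa_s) {
  if (any(is.na(t_sa_s)) || any(t_sa_s < 0))
    stop("t_sa_s must be non-negative and non-missing", call. = FALSE)
  findInterval(t_sa_s, c(0.100, 0.183, 0.267, 0.350))
}

#' Condition spectra via a nuisance-separating linear model
#'
#' Models the complex value of every spectral point, across metabolite
#' transients of one edit state, as a linear combination of condition
#' indicators (task-OFF plus the five stimulus-to-acquisition bins, or the
#' pooled task-ON column) and nuisance regressors: the phase-cycle sign,
#' the motion spike flag, and the standardised absolute registration
#' frequency and phase estimates. Condition coefficient spectra are
#' returned per edit state, and each difference (DIFF) spectrum is the
#' edit-ON condition coefficient minus the edit-OFF one.
#'
#' Transients flagged unusable by registration are excluded. Conditions
#' with no transients are flagged absent (`NULL` spectrum), not zero.
#'
#' @param series A `transient_series` (normally the aligned series from
#'   [register_spectra()]).
#' @param reg The registration estimates data frame from
#'   [register_spectra()]; `NULL` drops the motion regressors.
#' @param use_nuisance If `FALSE`, fits condition indicators only (plain
#'   per-condition means on a balanced design).
#' @param labels Optional custom condition labels, one per transient
#'   (water-reference entries ignored); overrides the default
#'   task-OFF/temporal-bin assignment, e.g. to model congruent vs
#'   incongruent-correct vs incongruent-incorrect trials. Custom condition
#'   DIFF spectra are returned in `diff_custom`.
#' @return An object of class `condition_spectra`: list with
#'   `diff_off_task`, `diff_bins` (list of 5, `NULL` where absent),
#'   `diff_on_pooled`, `editoff_off_task`, `editoff_on_pooled`,
#'   `editon_off_task`, a `counts` table of transients per condition and
#'   edit state, and `params`.
#' @export
fit_condition_glm <- function(series, reg = NULL, use_nuisance = TRUE,
                              labels = NULL) {
  sched <- series$schedule
  params <- series$params
  met <- which(!sched$is_wref)
  if (!is.null(reg)) met <- met[reg$usable[met]]
  if (!length(met)) stop("no usable metabolite transients", call. = FALSE)

  # condition labels: task-OFF, or temporal bin of the trial
  ton <- sched$task_state[met] == "ON"
  if (is.null(labels)) {
    cond <- rep("task_off", length(met))
    cond[ton] <- paste0("bin", assign_bin(sched$t_sa_s[met][ton]))
  } else {
    stopifnot(length(labels) == nrow(sched))
    cond <- labels[met]
    if (any(is.na(cond)))
      stop("custom labels must cover every metabolite transient",
           call. = FALSE)
  }
  cond_pooled <- ifelse(ton, "task_on", "task_off")

  nuisance <- function(rows) {
    if (!use_nuisance) return(NULL)
    X <- cbind(pc = ifelse(sched$phase_step[rows] == 0, 1, -1))
    if (!is.null(reg)) {
      std <- function(x) {
        s <- stats::sd(x)
        # a numerically constant column carries no motion information
        if (!is.finite(s) || s < 1e-4) return(NULL)
        (x - mean(x)) / s
      }
      cols <- list(spike = as.numeric(reg$spike_flag[rows]),
                   abs_freq = abs(reg$freq_offset_hz[rows]),
                   abs_phase = abs(reg$phase_deg[rows]))
      for (nm in names(cols)) {
        v <- std(cols[[nm]])
        if (!is.null(v)) {
          X <- cbind(X, v)
          colnames(X)[ncol(X)] <- nm
        }
      }
    }
    X
  }

  solve_glm <- function(rows, labels) {
    std_lev <- c("task_off", "task_on", paste0("bin", 0:4))
    lev <- c(std_lev[std_lev %in% unique(labels)],
             sort(setdiff(unique(labels), std_lev)))
    C <- stats::model.matrix(~ 0 + factor(labels, levels = lev))
    colnames(C) <- lev
    X <- C
    N <- nuisance(rows)
    if (!is.null(N)) {
      # the phase-cycle indicator is structural: collinearity is an error;
      # data-derived motion columns that add no rank are pruned instead
      for (j in seq_len(ncol(N))) {
        cand <- cbind(X, N[, j, drop = FALSE])
        if (qr(cand)$rank == ncol(cand)) {
          X <- cand
        } else if (colnames(N)[j] == "pc") {
          stop("rank-deficient condition design; collinear columns: pc",
               call. = FALSE)
        }
      }
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("rank-deficient condition design; collinear columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    Y <- t(apply(series$fids[rows, , drop = FALSE], 1, function(fid)
      fid_to_spectrum(fid, params)$values))
    beta <- qr.coef(qrX, Re(Y)) + 1i * qr.coef(qrX, Im(Y))
    rownames(beta) <- colnames(X)
    beta[lev, , drop = FALSE]
  }

  ppm <- fid_to_spectrum(series$fids[1, ], params)$ppm_axis
  as_spec <- function(v) mrs_spectrum(v, ppm, params$f0_mhz)

  out <- list(diff_bins = vector("list", 5L))
  counts <- list()
  beta_state <- list()
  for (state in c("ON", "OFF")) {
    rows_idx <- sched$edit_state[met] == state
    rows <- met[rows_idx]
    beta_state[[state]] <- list(
      binned = solve_glm(rows, cond[rows_idx]),
      pooled = solve_glm(rows, cond_pooled[rows_idx]))
    counts[[state]] <- table(factor(cond[rows_idx],
                                    levels = c("task_off", paste0("bin", 0:4))))
  }

  get_coef <- function(state, which_fit, name) {
    b <- beta_state[[state]][[which_fit]]
    if (!name %in% rownames(b)) return(NULL)
    b[name, ]
  }
  diff_coef <- function(which_fit, name) {
    on <- get_coef("ON", which_fit, name)
    off <- get_coef("OFF", which_fit, name)
    if (is.null(on) || is.null(off)) return(NULL)
    as_spec(on - off)
  }

  if (is.null(labels)) {
    out$diff_off_task <- diff_coef("binned", "task_off")
    for (b in 0:4) out$diff_bins[b + 1L] <- list(diff_coef("binned",
                                                           paste0("bin", b)))
  } else {
    lv <- unique(cond)
    out$diff_custom <- stats::setNames(
      lapply(lv, function(l) diff_coef("binned", l)), lv)
    out$diff_off_task <- out$diff_custom[["task_off"]]
  }
  out$diff_on_pooled <- diff_coef("pooled", "task_on")
  eo <- function(nm, fit) {
    v <- get_coef("OFF", fit, nm)
    if (is.null(v)) NULL else as_spec(v)
  }
  out$editoff_off_task <- eo("task_off", "binned")
  out$editoff_on_pooled <- eo("task_on", "pooled")
  v_on <- get_coef("ON", "binned", "task_off")
  out$editon_off_task <- if (is.null(v_on)) NULL else as_spec(v_on)
  out$counts <- do.call(rbind, counts)
  out$params <- params
  class(out) <- "condition_spectra"
  out
}

#' @export
print.condition_spectra <- function(x, ...) {
  cat("<condition_spectra>\n")
  print(x$counts)
  invisible(x)
}
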