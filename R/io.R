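# Plain-text serialisation: a transient series is stored as a directory
# holding a JSON header (acquisition parameters, and the subject truth for
# simulated data), the schedule as CSV, and the FIDs as a CSV of
# interleaved real/imaginary columns. Diff-friendly and dependency-free;
# subject tables and estimates are ordinary CSVs.

#' Write a transient series to a plain-text container
#'
#' @param series A `transient_series`.
#' @param path Directory to create (must not exist unless
#'   `overwrite = TRUE`).
#' @param overwrite Replace an existing container?
#' @return `path`, invisibly.
#' @export
write_transient_series <- function(series, path, overwrite = FALSE) {
  if (dir.exists(path) && !overwrite)
    stop("container already exists: ", path, call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(format = "megafmrs-transients", version = 1L,
                 params = unclass(series$params))
  if (!is.null(series$truth)) {
    header$truth <- unclass(series$truth)
    header$truth$behav <- NULL
  }
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(series$schedule),
                   file.path(path, "schedule.csv"), row.names = FALSE)
  fid_tab <- data.frame(re = as.vector(t(Re(series$fids))),
                        im = as.vector(t(Im(series$fids))))
  utils::write.csv(fid_tab, file.path(path, "fids.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a transient series from a plain-text container
#'
#' @param path Directory written by [write_transient_series()].
#' @return A `transient_series` (without per-transient ground truth).
#' @export
read_transient_series <- function(path) {
  hfile <- file.path(path, "header.json")
  if (!file.exists(hfile))
    stop("not a transient container (missing header.json): ", path,
         call. = FALSE)
  header <- jsonlite::read_json(hfile, simplifyVector = TRUE)
  if (!identical(header$format, "megafmrs-transients"))
    stop("unrecognised container format in ", hfile, call. = FALSE)
  params <- do.call(acq_params, header$params[names(header$params) %in%
                                                names(formals(acq_params))])
  sched <- utils::read.csv(file.path(path, "schedule.csv"),
                           stringsAsFactors = FALSE)
  class(sched) <- c("acq_schedule", "data.frame")
  fid_tab <- utils::read.csv(file.path(path, "fids.csv"))
  n <- nrow(sched)
  if (nrow(fid_tab) != n * params$n_points)
    stop("corrupt container: FID payload size does not match header",
         call. = FALSE)
  fids <- matrix(complex(real = fid_tab$re, imaginary = fid_tab$im),
                 nrow = n, ncol = params$n_points, byrow = TRUE)
  truth <- NULL
  if (!is.null(header$truth)) {
    tf <- header$truth[names(header$truth) %in%
                         names(formals(subject_truth))]
    truth <- do.call(subject_truth, tf)
  }
  structure(list(fids = fids, schedule = sched, params = params,
                 truth = truth, transient_truth = NULL),
            class = "transient_series")
}

# write cohort tables and a JSON manifest of model results
write_manifest <- function(manifest, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(manifest$subjects,
                   file.path(config$output_dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest$estimates,
                   file.path(config$output_dir, "estimates.csv"),
                   row.names = FALSE)
  slim <- manifest
  slim$subjects <- NULL
  slim$estimates <- NULL
  slim$qc_counts <- as.list(manifest$qc_counts)
  if (!is.null(slim$models))
    slim$models <- lapply(slim$models, function(m) {
      if (is.character(m)) return(list(error = m))
      list(terms = m$terms, n_used = m$n_used, dropped = m$dropped,
           diagnostics = as.list(m$diagnostics),
           warnings = m$warnings,
           percent_task_effect = m$percent_task_effect)
    })
  if (!is.null(slim$correlations))
    slim$correlations <- lapply(slim$correlations, unclass)
  jsonlite::write_json(slim, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(config$output_dir)
}
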