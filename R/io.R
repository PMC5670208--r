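#' Read and write pipeline data files
#'
#' Plain-text readers and writers for every exchange format the pipeline
#' consumes or emits: blood datasets (two CSVs in a directory), tissue TACs
#' (CSV), input functions (CSV plus a JSON fit report), skin-conductance
#' traces and stimulus/event tables (TSV), ratings tables (long CSV) and
#' association reports (JSON).
#'
#' @param x object to write.
#' @param path file path (or directory for blood datasets).
#' @return readers return the corresponding package object; writers return
#'   `path` invisibly.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
write_blood_dataset <- function(x, path) {
  stopifnot(inherits(x, "blood_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$continuous, file.path(path, "continuous.csv"), row.names = FALSE)
  utils::write.csv(x$discrete, file.path(path, "discrete.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_blood_dataset <- function(path) {
  cont <- utils::read.csv(file.path(path, "continuous.csv"))
  disc <- utils::read.csv(file.path(path, "discrete.csv"))
  stopifnot(all(c("time_s", "whole_blood") %in% names(cont)),
            all(c("time_min", "whole_blood", "plasma", "parent_fraction") %in% names(disc)))
  .check_increasing(cont$time_s, "continuous time")
  .check_increasing(disc$time_min, "discrete time")
  if (any(cont$whole_blood < 0) || any(disc$plasma < 0, na.rm = TRUE))
    .stopf("negative activity in blood dataset")
  pf <- disc$parent_fraction
  if (any(pf < 0 | pf > 1, na.rm = TRUE)) .stopf("parent fraction outside [0, 1]")
  structure(list(continuous = cont, discrete = disc, params = NULL),
            class = "blood_dataset")
}

#' @rdname pipeline-io
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tissue_tac"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_tac <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("frame_start_s", "frame_dur_s", "activity") %in% names(d)))
  if (!"trues_rate" %in% names(d)) d$trues_rate <- NA_real_
  structure(d, class = c("tissue_tac", "data.frame"))
}

#' @rdname pipeline-io
#' @export
write_input_function <- function(x, path) {
  stopifnot(inherits(x, "input_function"))
  utils::write.csv(data.frame(time_s = x$time_s,
                              parent_plasma_activity = x$parent_plasma_activity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_input_function <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "parent_plasma_activity") %in% names(d)))
  .check_increasing(d$time_s, "input function time")
  if (any(d$parent_plasma_activity < 0)) .stopf("negative input activity")
  structure(d, delay_applied = 0, class = c("input_function", "data.frame"))
}

#' Write a JSON report of the input-function fits
#'
#' @param ratio_model,parent_model the fitted sigmoids.
#' @param delay_s applied arrival delay in seconds.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_input_fit_report <- function(ratio_model, parent_model, delay_s, path) {
  rep <- list(
    ratio_sigmoid = as.list(ratio_model$par),
    ratio_rss = ratio_model$rss,
    parent_sigmoid = as.list(parent_model$par),
    parent_rss = parent_model$rss,
    delay_s = delay_s,
    delay_objective = "weighted spectral-fit residual of the whole-brain TAC"
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a spectral fit as JSON
#'
#' @param fit a `spectral_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectral_fit <- function(fit, path) {
  stopifnot(inherits(fit, "spectral_fit"))
  jsonlite::write_json(
    list(alpha = fit$alpha, beta = fit$beta, vb = fit$vb, vt = fit$vt,
         irf_60min = fit$irf_60min, weighted_rss = fit$weighted_rss,
         regularisation = fit$regularisation, units = fit$units),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
write_scr_session <- function(x, path) {
  stopifnot(inherits(x, "scr_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$trace, file.path(path, "trace.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(x$stimuli, file.path(path, "stimuli.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(x$events, file.path(path, "events_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_scr_trace <- function(path) {
  d <- utils::read.delim(path)
  stopifnot(all(c("time_s", "conductance_uS") %in% names(d)))
  d
}

#' @rdname pipeline-io
#' @export
read_stimuli <- function(path) {
  d <- utils::read.delim(path)
  stopifnot(all(c("onset_s", "valence") %in% names(d)))
  d
}

#' @rdname pipeline-io
#' @export
write_ratings <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_ratings <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("subject", "condition", "scale", "time_h", "value") %in% names(d)))
  structure(d, class = c("ratings_table", "data.frame"))
}

#' @rdname pipeline-io
#' @export
write_association_report <- function(x, path) {
  stopifnot(inherits(x, "association_report"))
  jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
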