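#' Fit the plasma-to-blood ratio sigmoid
#'
#' Fits [fit_sigmoid()] to the plasma / whole-blood ratio of the first six
#' discrete arterial samples (3, 5, 10, 15, 20 and 30 min), the samples used
#' to convert the continuous whole-blood record into plasma activity.
#'
#' @param blood a `blood_dataset` (see [gen_blood_dataset()] or
#'   [read_blood_dataset()]).
#' @return a `sigmoid_model` of ratio versus time in minutes.
#' @export
fit_plasma_ratio <- function(blood) {
  stopifnot(inherits(blood, "blood_dataset"))
  d <- blood$discrete
  d <- d[d$time_min <= 30, , drop = FALSE]
  d <- utils::head(d[order(d$time_min), ], 6L)
  if (nrow(d) < 5L) .stopf("need >= 5 early discrete samples for the ratio fit")
  if (any(d$whole_blood <= 0)) .stopf("non-positive whole blood at a discrete sample")
  fit_sigmoid(d$time_min, d$plasma / d$whole_blood)
}

#' Fit the parent-fraction sigmoid
#'
#' Fits the four-parameter sigmoid to every discrete sample with a measured
#' parent fraction (samples where metabolite assay was impossible, e.g. the
#' 90-min draw, are excluded automatically).
#'
#' @inheritParams fit_plasma_ratio
#' @return a `sigmoid_model` of parent fraction versus time in minutes.
#' @export
fit_parent_fraction <- function(blood) {
  stopifnot(inherits(blood, "blood_dataset"))
  d <- blood$discrete
  d <- d[!is.na(d$parent_fraction), , drop = FALSE]
  if (nrow(d) < 5L) .stopf("need >= 5 parent-fraction measurements")
  if (any(d$parent_fraction < 0 | d$parent_fraction > 1))
    .stopf("parent fractions must lie in [0, 1]")
  fit_sigmoid(d$time_min, d$parent_fraction)
}

#' Build the total plasma activity curve
#'
#' Converts the continuous whole-blood record (first 15 min) into plasma by
#' multiplying with the fitted plasma-to-blood ratio, then merges the late
#' discrete plasma samples -- whichever of the 20, 30, 50, 60, 75 (and, if
#' supplied, 90) minute draws are present -- into a single strictly
#' increasing time grid. Interpolation between merged breakpoints is
#' piecewise linear.
#'
#' @param blood a `blood_dataset`.
#' @param ratio_model a `sigmoid_model` from [fit_plasma_ratio()]; fitted
#'   automatically when `NULL`.
#' @return a `plasma_curve`: data frame `time_s`, `plasma` with the source
#'   whole-blood dataset attached as attribute `blood`.
#' @export
build_plasma_curve <- function(blood, ratio_model = NULL) {
  stopifnot(inherits(blood, "blood_dataset"))
  if (is.null(ratio_model)) ratio_model <- fit_plasma_ratio(blood)
  stopifnot(inherits(ratio_model, "sigmoid_model"))

  cont <- blood$continuous
  ratio <- predict(ratio_model, cont$time_s / 60)
  if (any(ratio < 0)) .stopf("ratio model produces negative ratios")
  cont_plasma <- cont$whole_blood * ratio

  merge_min <- c(20, 30, 50, 60, 75, 90)
  d <- blood$discrete
  late <- d[d$time_min %in% merge_min & d$time_min * 60 > max(cont$time_s), , drop = FALSE]
  missing <- setdiff(c(20, 30, 50, 60, 75), d$time_min)
  if (length(missing))
    message("plasma merge: no discrete sample at ", paste(missing, collapse = ", "), " min")

  out <- data.frame(
    time_s = c(cont$time_s, late$time_min * 60),
    plasma = c(cont_plasma, late$plasma)
  )
  out <- out[order(out$time_s), ]
  out <- out[!duplicated(out$time_s), ]
  rownames(out) <- NULL
  .check_increasing(out$time_s, "merged plasma time grid")
  structure(out, blood = blood, class = c("plasma_curve", "data.frame"))
}

#' Metabolite-correct a plasma curve into the parent input function
#'
#' Multiplies total plasma activity pointwise by the fitted parent-fraction
#' sigmoid (clipped to [0, 1]) to obtain the activity of unmetabolised
#' tracer in plasma -- the input function driving all kinetic analyses.
#'
#' @param plasma_curve a `plasma_curve` from [build_plasma_curve()].
#' @param parent_model a `sigmoid_model` from [fit_parent_fraction()].
#' @return an `input_function`: data frame `time_s`,
#'   `parent_plasma_activity`, with attribute `delay_applied` (seconds, 0
#'   until [apply_delay()] is used).
#' @export
apply_parent_correction <- function(plasma_curve, parent_model) {
  stopifnot(inherits(plasma_curve, "plasma_curve"),
            inherits(parent_model, "sigmoid_model"))
  pf <- pmin(pmax(predict(parent_model, plasma_curve$time_s / 60), 0), 1)
  out <- data.frame(
    time_s = plasma_curve$time_s,
    parent_plasma_activity = plasma_curve$plasma * pf
  )
  structure(out,
            blood = attr(plasma_curve, "blood"),
            delay_applied = 0,
            class = c("input_function", "data.frame"))
}

#' Shift an input function in time
#'
#' Applies a tracer-arrival delay: positive `delay_s` means the bolus
#' reached the peripheral sampling site `delay_s` seconds after the brain,
#' so the corrected brain input is the measured curve evaluated at
#' `t + delay_s`. The applied delay is accumulated in the `delay_applied`
#' attribute.
#'
#' @param input_function an `input_function`.
#' @param delay_s delay in seconds.
#' @return the shifted `input_function`.
#' @export
apply_delay <- function(input_function, delay_s) {
  stopifnot(inherits(input_function, "input_function"))
  .check_finite(delay_s, "delay_s")
  t <- input_function$time_s
  shifted <- .extend_curve(t, input_function$parent_plasma_activity, t + delay_s)
  shifted[shifted < 0] <- 0
  out <- data.frame(time_s = t, parent_plasma_activity = shifted)
  structure(out,
            blood = attr(input_function, "blood"),
            delay_applied = (attr(input_function, "delay_applied") %||% 0) + delay_s,
            class = c("input_function", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate the blood-to-brain tracer arrival delay
#'
#' Grid search over candidate delays: for each shift the whole-brain
#' time-activity curve is fitted by spectral analysis against the shifted
#' input and the delay minimising the weighted residual sum of squares is
#' returned. The fitted delay is conventionally fixed for the entire brain.
#' A boundary optimum, or an essentially flat objective (relative RSS range
#' below 0.1%), is signalled with a warning.
#'
#' @param input_function an `input_function`.
#' @param whole_brain_tac a `tissue_tac` (or numeric activity vector).
#' @param schedule the acquisition [frame_schedule()].
#' @param delays candidate delays in seconds (default -30 to +30 by 0.5).
#' @param n_beta size of the spectral grid used for the search fits
#'   (default 40; the search needs relative, not absolute, fit quality).
#' @param weights optional frame weights; defaults to [frame_weights()] when
#'   the schedule has trues, otherwise the frame durations.
#' @return list with `delay_s` (the estimate) and `grid` (data frame
#'   `delay_s`, `rss`).
#' @export
estimate_delay <- function(input_function, whole_brain_tac, schedule,
                           delays = seq(-30, 30, by = 0.5),
                           n_beta = 40, weights = NULL) {
  stopifnot(inherits(input_function, "input_function"),
            inherits(schedule, "frame_schedule"))
  .check_finite(delays, "delays")
  y <- if (is.data.frame(whole_brain_tac)) whole_brain_tac$activity else whole_brain_tac
  if (is.null(weights)) {
    weights <- if (all(!is.na(schedule$trues_rate))) frame_weights(schedule)
               else schedule$frame_dur_s
  }
  rss <- vapply(delays, function(d) {
    basis <- build_basis(apply_delay(input_function, d), schedule, n_beta = n_beta)
    fit_spectral(y, basis, weights = weights, vb = 0)$weighted_rss
  }, numeric(1))
  i <- which.min(rss)
  if (i == 1L || i == length(delays))
    .warnf("delay optimum at search-grid boundary (%g s)", delays[i])
  rng <- range(rss)
  if (rng[1] > 0 && diff(rng) / rng[1] < 1e-3)
    .warnf("delay objective is essentially flat; estimate unreliable")
  list(delay_s = delays[i], grid = data.frame(delay_s = delays, rss = rss))
}
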