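#' Physical decay constant from an isotope half-life
#'
#' Converts a half-life in minutes to a per-second decay constant
#' `ln(2) / (half_life * 60)`. For carbon-11 (half-life 20.4 min) this gives
#' 0.0005663 s^-1 (log10 = -3.25), which anchors the slow frequency boundary
#' of the spectral basis: no tissue kinetic can be slower than the physical
#' decay of the label.
#'
#' @param half_life_minutes isotope half-life in minutes, > 0.
#' @return decay constant in s^-1.
#' @examples
#' decay_constant(20.4)
#' @export
decay_constant <- function(half_life_minutes) {
  if (!is.numeric(half_life_minutes) || length(half_life_minutes) != 1L ||
      !is.finite(half_life_minutes) || half_life_minutes <= 0)
    .stopf("half_life_minutes must be a single positive number")
  log(2) / (half_life_minutes * 60)
}

#' Construct a PET frame schedule
#'
#' A frame schedule is the timing backbone of a dynamic PET acquisition:
#' contiguous, non-overlapping frames described by start time and duration,
#' optionally with the scanner's rate of true coincidences per frame (the
#' source of statistical frame weights).
#'
#' @param frame_durations frame lengths L_i in seconds, all > 0.
#' @param trues_rate optional true-coincidence rates T_i in counts/s
#'   (one per frame, >= 0).
#' @param t0 start of the first frame in seconds (default 0).
#' @return a `frame_schedule` data frame with columns `frame_start_s`,
#'   `frame_dur_s`, `frame_mid_s` and `trues_rate`.
#' @seealso [meppep_frame_schedule()] for the 35-frame, 95-minute schedule
#'   used throughout the package's examples, [frame_weights()].
#' @export
frame_schedule <- function(frame_durations, trues_rate = NULL, t0 = 0) {
  .check_finite(frame_durations, "frame_durations")
  if (any(frame_durations <= 0)) .stopf("frame durations must be > 0")
  n <- length(frame_durations)
  if (is.null(trues_rate)) trues_rate <- rep(NA_real_, n)
  if (length(trues_rate) != n) .stopf("trues_rate must have one value per frame")
  if (any(trues_rate < 0, na.rm = TRUE)) .stopf("trues rates must be >= 0")
  start <- t0 + cumsum(c(0, frame_durations[-n]))
  out <- data.frame(
    frame_start_s = start,
    frame_dur_s = frame_durations,
    frame_mid_s = start + frame_durations / 2,
    trues_rate = as.numeric(trues_rate)
  )
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' The 35-frame, 95-minute rebinning schedule
#'
#' One 30-second background frame, six 10-s, three 20-s, three 30-s, four
#' 60-s, six 120-s, nine 300-s and three 600-s frames: 35 frames covering 95
#' minutes of list-mode emission data.
#'
#' @inheritParams frame_schedule
#' @return a `frame_schedule` of 35 frames totalling 5700 s.
#' @export
meppep_frame_schedule <- function(trues_rate = NULL) {
  frame_schedule(
    c(30, rep(10, 6), rep(20, 3), rep(30, 3), rep(60, 4),
      rep(120, 6), rep(300, 9), rep(600, 3)),
    trues_rate = trues_rate
  )
}

#' Statistical frame weights w_i = L_i / T_i
#'
#' Weights proportional to the reciprocal of the frame variance, estimated
#' from the scanner's rate of true coincidences T_i (counts/s) and the frame
#' length L_i (s). Frames with zero trues carry no information and receive
#' weight 0 (with a warning) rather than an infinite variance.
#'
#' @param schedule a [frame_schedule()] whose `trues_rate` column is filled,
#'   or a `tissue_tac` (which carries frame durations and trues rates).
#' @return numeric vector of non-negative weights, one per frame.
#' @export
frame_weights <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule") || inherits(schedule, "tissue_tac"))
  t_rate <- schedule$trues_rate
  if (any(is.na(t_rate))) .stopf("schedule has no trues_rate; weights undefined")
  if (any(t_rate < 0)) .stopf("negative trues rate")
  w <- schedule$frame_dur_s / t_rate
  zero <- t_rate == 0
  if (any(zero)) {
    .warnf("%d frame(s) with zero trues assigned weight 0", sum(zero))
    w[zero] <- 0
  }
  w
}
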