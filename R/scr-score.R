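#' Detect stimulus-locked skin-conductance fluctuations
#'
#' Scores each stimulus by the explicit electrodermal rule: a fluctuation is
#' an unambiguous rise of at least `threshold` (0.01 microsiemens) with
#' respect to the pre-stimulus baseline, whose first rising data point falls
#' 0.5-3 s after the stimulus. The amplitude is the conductance difference
#' from the onset level (the sample before the first rising data point) to
#' the fluctuation peak; the latency is the time of the first rising sample
#' relative to the stimulus. At most one event -- the first qualifying rise
#' -- is scored per stimulus.
#'
#' The trace is smoothed with a causal moving average (`smooth_s`) before
#' differencing so sensor noise does not masquerade as rises, and a sample
#' only opens a candidate rise when the smoothed slope exceeds `min_slope`,
#' which keeps slow tonic drift from anchoring onsets at the window edge.
#'
#' @param trace an `scr_session`, or a data frame with `time_s` and
#'   `conductance_uS` sampled at >= 2 Hz.
#' @param stimuli data frame with `onset_s` (and optionally `valence`);
#'   taken from the session when omitted.
#' @param window onset acceptance window, seconds post-stimulus.
#' @param threshold minimum rise in microsiemens (default 0.01).
#' @param baseline_s width of the pre-stimulus baseline window, seconds.
#' @param smooth_s causal moving-average width, seconds (0 disables).
#' @param min_slope minimum smoothed slope (uS/s) opening a candidate rise.
#' @param max_peak_s how far past the onset the peak is searched, seconds.
#' @param window_anchor apply the 0.5-3 s window to the rise `"onset"`
#'   (default) or to the `"peak"`.
#' @param require_above_baseline additionally require the peak to exceed the
#'   pre-stimulus baseline mean by `threshold`. Off by default: the
#'   operative criterion is the onset-to-peak rise (trough-to-peak
#'   convention), because decay superposed from a preceding response can
#'   hold the pre-stimulus mean above a genuine later fluctuation.
#' @return an `scr_events` data frame: `stimulus_index`, `onset_s`,
#'   `latency_s`, `amplitude_uS`, `peak_time_s`, `rise_time_s`, `valence`.
#'   Rise time is emitted per event but enters no downstream statistic.
#' @export
detect_scr_events <- function(trace, stimuli = NULL,
                              window = c(0.5, 3), threshold = 0.01,
                              baseline_s = 1, smooth_s = 0.25,
                              min_slope = 0.005, max_peak_s = 4,
                              window_anchor = c("onset", "peak"),
                              require_above_baseline = FALSE) {
  window_anchor <- match.arg(window_anchor)
  if (inherits(trace, "scr_session")) {
    if (is.null(stimuli)) stimuli <- trace$stimuli
    trace <- trace$trace
  }
  stopifnot(is.data.frame(trace), all(c("time_s", "conductance_uS") %in% names(trace)),
            is.data.frame(stimuli), "onset_s" %in% names(stimuli))
  t <- trace$time_s
  x <- trace$conductance_uS
  .check_finite(x, "conductance")
  dt <- stats::median(diff(t))
  fs <- 1 / dt
  if (fs < 2) .stopf("sampling rate must be >= 2 Hz (got %.2f)", fs)
  if (any(stimuli$onset_s < t[1] | stimuli$onset_s > t[length(t)]))
    .stopf("stimulus outside the trace duration")

  k <- max(1L, round(smooth_s * fs))
  xs <- if (k > 1L) as.numeric(stats::filter(x, rep(1 / k, k), sides = 1)) else x
  xs[seq_len(min(k - 1L, length(xs)))] <- x[seq_len(min(k - 1L, length(xs)))]
  slope <- c(diff(xs), 0) * fs      # forward-difference slope at each sample
  slope_raw <- c(diff(x), 0) * fs

  valence <- if ("valence" %in% names(stimuli)) stimuli$valence
             else rep(NA_character_, nrow(stimuli))
  out <- list()
  for (s in seq_len(nrow(stimuli))) {
    t0 <- stimuli$onset_s[s]
    if (t0 + window[2] > t[length(t)]) {
      .warnf("stimulus %d closer than the scoring window to trace end; skipped", s)
      next
    }
    base_idx <- which(t >= t0 - baseline_s & t < t0)
    baseline <- if (length(base_idx)) mean(xs[base_idx]) else xs[which.min(abs(t - t0))]
    win_idx <- which(t - t0 >= window[1] & t - t0 <= window[2])
    if (!length(win_idx)) next
    rising <- win_idx[slope[pmax(win_idx - 1L, 1L)] > min_slope]
    if (!length(rising)) next
    # candidate onsets: first sample of each maximal run of rising samples
    starts <- rising[c(TRUE, diff(rising) > 1L)]
    for (j in starts) {
      # the smoothing window lags the detection; walk back to the first
      # genuinely rising raw sample so the scored onset is the rise start
      while (j > 2L && slope_raw[j - 2L] > min_slope &&
             t[j - 1L] - t0 >= window[1]) j <- j - 1L
      peak_lim <- min(length(xs), j + round(max_peak_s * fs))
      seg <- xs[j:peak_lim]
      pk_rel <- which.max(seg)
      pk <- j + pk_rel - 1L
      onset_level <- xs[j - 1L]
      amplitude <- xs[pk] - onset_level
      if (amplitude < threshold) next
      if (require_above_baseline && xs[pk] - baseline < threshold) next
      anchor_t <- if (window_anchor == "onset") t[j] else t[pk]
      if (anchor_t - t0 < window[1] || anchor_t - t0 > window[2]) next
      out[[length(out) + 1L]] <- data.frame(
        stimulus_index = s,
        onset_s = t[j],
        latency_s = t[j] - t0,
        amplitude_uS = amplitude,
        peak_time_s = t[pk],
        rise_time_s = t[pk] - t[j],
        valence = valence[s]
      )
      break   # at most one event per stimulus: the first qualifying rise
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(stimulus_index = integer(), onset_s = numeric(),
               latency_s = numeric(), amplitude_uS = numeric(),
               peak_time_s = numeric(), rise_time_s = numeric(),
               valence = character())
  structure(res, class = c("scr_events", "data.frame"))
}

#' Summarise scored skin-conductance events
#'
#' Counts and mean amplitude/latency per grouping cell. Cells without any
#' event report a count of 0 and missing (`NA`) amplitude and latency,
#' never a zero amplitude.
#'
#' @param events an `scr_events` table from [detect_scr_events()]; a
#'   `condition` column (e.g. drug/placebo) may be added for mixed-session
#'   summaries.
#' @param stimuli the stimulus table that was scored (defines the cells for
#'   valence); may also carry a `condition` column.
#' @param grouping `"valence"`, `"condition"` or `"valence_condition"`.
#' @return data frame with one row per cell: grouping columns, `n_events`,
#'   `mean_amplitude_uS`, `mean_latency_s`.
#' @export
summarize_scr <- function(events, stimuli,
                          grouping = c("valence", "condition", "valence_condition")) {
  grouping <- match.arg(grouping)
  cols <- switch(grouping,
                 valence = "valence",
                 condition = "condition",
                 valence_condition = c("valence", "condition"))
  for (cl in cols) {
    if (!cl %in% names(stimuli)) .stopf("stimuli lack a '%s' column", cl)
    if (!cl %in% names(events) && nrow(events)) .stopf("events lack a '%s' column", cl)
  }
  cells <- unique(stimuli[, cols, drop = FALSE])
  cells <- cells[do.call(order, as.list(cells)), , drop = FALSE]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(events))
    for (cl in cols) sel <- sel & events[[cl]] == cells[[cl]][i]
    e <- events[sel, , drop = FALSE]
    data.frame(cells[i, , drop = FALSE],
               n_events = nrow(e),
               mean_amplitude_uS = if (nrow(e)) mean(e$amplitude_uS) else NA_real_,
               mean_latency_s = if (nrow(e)) mean(e$latency_s) else NA_real_,
               row.names = NULL)
  })
  do.call(rbind, res)
}
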