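#' Default parameters for the skin-conductance generator
#'
#' Transients are difference-of-exponentials (rise 0.75 s, decay 2 s),
#' amplitudes lognormal above a floor, onset latencies uniform in the
#' scoring window 0.5-3 s after the stimulus; the tonic level drifts slowly
#' (gentle sinusoid plus linear trend) so that scored fluctuations are
#' baseline-relative, not absolute.
#'
#' @return named list of generator parameters for [gen_scr_session()].
#' @export
scr_session_defaults <- function() {
  list(
    sampling_rate = 20,        # Hz
    response_prob = 0.8,       # proportion of stimuli eliciting an SCR
    amp_floor = 0.02,          # uS; minimum transient amplitude
    amp_meanlog = log(0.08),   # lognormal amplitude above the floor
    amp_sdlog = 0.5,
    fear_amp_offset = 0,       # uS added to fearful-stimulus amplitudes
    latency_range = c(0.5, 3), # s post-stimulus
    rise_tau = 0.75,           # s
    decay_tau = 2,             # s
    tonic_level = 2,           # uS
    drift_amp = 0.03,          # uS; slow sinusoidal drift
    drift_period = 180,        # s
    drift_slope = 2e-4,        # uS/s linear trend
    noise_sd = 0,              # uS additive sensor noise
    min_isi = 2.5,             # s; stimuli closer than this are rejected
    tail_s = 15                # trace continues this long after last stimulus
  )
}

#' Generate a synthetic skin-conductance session
#'
#' Produces a conductance trace (tonic drift plus stimulus-locked
#' transients) together with the ground-truth event table, for testing the
#' rule-based scorer. A configurable proportion of stimuli elicit a
#' response; fearful stimuli can carry an amplitude offset over neutral
#' ones.
#'
#' @param stimuli data frame with `onset_s` and `valence`
#'   (`"neutral"`/`"fearful"`).
#' @param params list as from [scr_session_defaults()]; partial lists are
#'   merged over the defaults.
#' @param seed integer seed.
#' @return an `scr_session`: list with `trace` (data frame `time_s`,
#'   `conductance_uS`), `events` (ground truth: `stimulus_index`, `onset_s`,
#'   `latency_s`, `amplitude_uS`, `valence`), `stimuli`, `params`.
#' @export
gen_scr_session <- function(stimuli, params = list(), seed = NULL) {
  p <- utils::modifyList(scr_session_defaults(), params)
  stopifnot(is.data.frame(stimuli), all(c("onset_s", "valence") %in% names(stimuli)))
  .check_finite(stimuli$onset_s, "stimulus onsets")
  ons <- stimuli$onset_s
  if (is.unsorted(ons)) .stopf("stimulus onsets must be sorted")
  if (any(diff(ons) < p$min_isi))
    .stopf("stimuli closer than the minimum ISI of %g s", p$min_isi)
  if (!is.null(seed)) set.seed(seed)

  fs <- p$sampling_rate
  t <- seq(0, max(ons) + p$tail_s, by = 1 / fs)
  g <- p$tonic_level + p$drift_amp * sin(2 * pi * t / p$drift_period) +
    p$drift_slope * t
  if (p$noise_sd > 0) g <- g + stats::rnorm(length(t), 0, p$noise_sd)

  # unit-peak difference-of-exponentials transient
  kernel <- function(tt) {
    h <- exp(-tt / p$decay_tau) - exp(-tt / p$rise_tau)
    tpk <- log(p$decay_tau / p$rise_tau) / (1 / p$rise_tau - 1 / p$decay_tau)
    hmax <- exp(-tpk / p$decay_tau) - exp(-tpk / p$rise_tau)
    ifelse(tt < 0, 0, h / hmax)
  }

  n_stim <- nrow(stimuli)
  respond <- stats::runif(n_stim) < p$response_prob
  # latencies are quantised to the sampling grid and kept one sample inside
  # the window so that every ground-truth event is scorable from the
  # sampled trace (a rise starting within the last sample of the window
  # cannot be resolved at the trace resolution)
  lat <- stats::runif(n_stim, p$latency_range[1], p$latency_range[2] - 2 / fs)
  lat <- round((ons + lat) * fs) / fs - ons
  amp <- p$amp_floor + stats::rlnorm(n_stim, p$amp_meanlog, p$amp_sdlog) +
    ifelse(stimuli$valence == "fearful", p$fear_amp_offset, 0)

  events <- data.frame(stimulus_index = integer(), onset_s = numeric(),
                       latency_s = numeric(), amplitude_uS = numeric(),
                       valence = character())
  for (i in seq_len(n_stim)) {
    if (!respond[i]) next
    onset <- ons[i] + lat[i]
    g <- g + amp[i] * kernel(t - onset)
    events <- rbind(events, data.frame(
      stimulus_index = i, onset_s = onset, latency_s = lat[i],
      amplitude_uS = amp[i], valence = stimuli$valence[i]))
  }

  structure(list(
    trace = data.frame(time_s = t, conductance_uS = g),
    events = events,
    stimuli = stimuli,
    params = p
  ), class = "scr_session")
}

#' @export
print.scr_session <- function(x, ...) {
  cat(sprintf("scr_session: %.0f s at %g Hz, %d stimuli, %d ground-truth events\n",
              max(x$trace$time_s), x$params$sampling_rate,
              nrow(x$stimuli), nrow(x$events)))
  invisible(x)
}

#' Build an evenly spaced stimulus table
#'
#' Convenience constructor for the fear-processing design: alternating (or
#' randomised) neutral/fearful face onsets with a fixed or jittered
#' inter-stimulus interval. Stimulus count and session duration are both
#' free: the task's printed arithmetic (60 two-second stimuli at a mean ISI
#' of 5.9 s versus a 6-minute run) does not pin them jointly, so neither is
#' enforced.
#'
#' @param n_stimuli number of stimuli.
#' @param isi_s inter-stimulus onset interval, seconds.
#' @param start_s onset of the first stimulus.
#' @param valence `"alternating"` or a character vector recycled over
#'   stimuli.
#' @return data frame `onset_s`, `valence`.
#' @export
make_stimulus_table <- function(n_stimuli = 60, isi_s = 7.9, start_s = 10,
                                valence = "alternating") {
  if (identical(valence, "alternating"))
    valence <- rep(c("neutral", "fearful"), length.out = n_stimuli)
  data.frame(onset_s = start_s + (seq_len(n_stimuli) - 1) * isi_s,
             valence = rep(valence, length.out = n_stimuli))
}
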