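#' Default arterial blood profile parameters
#'
#' The whole-blood curve is a bolus-shaped gamma-variate peak (injection as a
#' smooth bolus ~30 s after scan start) plus a slowly washing-out
#' recirculation tail. The plasma-to-blood ratio and the parent
#' (unmetabolised tracer) fraction are four-parameter sigmoids of time in
#' minutes: the ratio drifts from its early value towards a late plateau,
#' and the parent fraction falls from 1 as metabolites appear.
#'
#' @return named list of profile parameters accepted by
#'   [gen_blood_dataset()]; override any element to change the profile.
#' @export
blood_profile_defaults <- function() {
  list(
    wb_peak = 75,            # kBq/ml at the bolus peak
    wb_t0_s = 30,            # injection start, s after scan start
    wb_peak_time_s = 35,     # time-to-peak after injection, s
    wb_shape = 2.5,          # gamma-variate shape of the bolus
    wb_tail_frac = 0.2,      # recirculation fraction of the peak
    wb_tail_rise_s = 60,     # recirculation rise constant, s
    wb_tail_decay_s = 2400,  # recirculation washout constant, s
    ratio = c(a = 1.25, b = 0.75, c = 6, d = 1.8),   # plasma/blood vs min
    parent = c(a = 0.10, b = 1.00, c = 18, d = 2.2), # parent fraction vs min
    noise_cv = 0,            # multiplicative noise CV on discrete samples
    sample_times_min = c(3, 5, 10, 15, 20, 30, 50, 75),
    include_90min = TRUE     # plasma/whole-blood only; no parent at 90 min
  )
}

.wb_curve <- function(t_s, p) {
  tt <- t_s - p$wb_t0_s
  g <- ifelse(tt <= 0, 0, (tt / p$wb_peak_time_s)^p$wb_shape *
                exp(p$wb_shape * (1 - tt / p$wb_peak_time_s)))
  tail <- ifelse(tt <= 0, 0, (1 - exp(-tt / p$wb_tail_rise_s)) *
                   exp(-tt / p$wb_tail_decay_s))
  p$wb_peak * ((1 - p$wb_tail_frac) * g + p$wb_tail_frac * tail)
}

#' Generate a synthetic arterial blood dataset
#'
#' Emulates the blood side of a dynamic PET study: a continuous whole-blood
#' curve from an on-line detector (0-15 min, 1-s resolution) and discrete
#' heparinised samples at 3, 5, 10, 15, 20, 30, 50 and 75 min (plus an
#' optional 90-min sample at which the parent fraction cannot be assayed).
#' Discrete plasma equals whole blood times the generating ratio sigmoid;
#' the parent fraction follows the generating parent sigmoid, so the input
#' function module can be validated by round trip.
#'
#' @param profile_params list as from [blood_profile_defaults()]; partial
#'   lists are merged over the defaults.
#' @param seed integer seed for the (optional) sampling noise.
#' @return a `blood_dataset`: list with `continuous` (data frame `time_s`,
#'   `whole_blood`), `discrete` (data frame `time_min`, `whole_blood`,
#'   `plasma`, `parent_fraction`) and the generating `params`.
#' @export
gen_blood_dataset <- function(profile_params = list(), seed = NULL) {
  p <- utils::modifyList(blood_profile_defaults(), profile_params)
  num <- unlist(p[c("wb_peak", "wb_t0_s", "wb_peak_time_s", "wb_shape",
                    "wb_tail_frac", "wb_tail_decay_s", "ratio", "parent")])
  if (any(!is.finite(num))) .stopf("non-finite blood profile parameter")
  if (p$wb_peak < 0) .stopf("negative blood activity")
  if (!is.null(seed)) set.seed(seed)

  t_cont <- seq(0, 900, by = 1)
  cont <- data.frame(time_s = t_cont, whole_blood = .wb_curve(t_cont, p))

  tm <- sort(p$sample_times_min)
  if (p$include_90min) tm <- c(tm, 90)
  wb <- .wb_curve(tm * 60, p)
  ratio <- logistic4(tm, p$ratio[["a"]], p$ratio[["b"]], p$ratio[["c"]], p$ratio[["d"]])
  if (any(ratio < 0)) .stopf("ratio sigmoid produced negative values")
  parent <- pmin(pmax(logistic4(tm, p$parent[["a"]], p$parent[["b"]],
                                p$parent[["c"]], p$parent[["d"]]), 0), 1)
  if (p$include_90min) parent[length(parent)] <- NA_real_

  if (p$noise_cv > 0) {
    sdlog <- sqrt(log(1 + p$noise_cv^2))
    wb <- wb * stats::rlnorm(length(wb), -sdlog^2 / 2, sdlog)
  }
  plasma <- wb * ratio

  structure(list(
    continuous = cont,
    discrete = data.frame(time_min = tm, whole_blood = wb, plasma = plasma,
                          parent_fraction = parent),
    params = p
  ), class = "blood_dataset")
}

#' @export
print.blood_dataset <- function(x, ...) {
  cat(sprintf("blood_dataset: continuous 0-%g s (%d points), %d discrete samples\n",
              max(x$continuous$time_s), nrow(x$continuous), nrow(x$discrete)))
  print(x$discrete, row.names = FALSE)
  invisible(x)
}
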