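#' Compartment-model parameters for TAC simulation
#'
#' Ground-truth kinetic parameters for the synthetic tissue generator. Rate
#' constants are in conventional per-minute units (`K1` ml/g/min, `k2`-`k4`
#' 1/min); `vb` is the vascular fraction of the measured signal and
#' `delay_s` the blood-to-brain arrival delay in seconds.
#'
#' @param model `"one_tissue"` or `"two_tissue"` (reversible).
#' @param K1,k2,k3,k4 rate constants, > 0 where required by the model.
#' @param vb blood volume fraction in [0, 1].
#' @param delay_s arrival delay, seconds (positive: blood sampling site lags
#'   the brain).
#' @return a `kinetic_params` list.
#' @seealso [analytic_vt()] for the implied volume of distribution.
#' @export
kinetic_params <- function(model = c("one_tissue", "two_tissue"),
                           K1, k2, k3 = NULL, k4 = NULL,
                           vb = 0, delay_s = 0) {
  model <- match.arg(model)
  chk <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x <= 0) .stopf("%s must be > 0", nm)
    x
  }
  chk(K1, "K1"); chk(k2, "k2")
  if (model == "two_tissue") { chk(k3, "k3"); chk(k4, "k4") }
  if (!is.finite(vb) || vb < 0 || vb > 1) .stopf("vb must lie in [0, 1]")
  structure(list(model = model, K1 = K1, k2 = k2, k3 = k3, k4 = k4,
                 vb = vb, delay_s = delay_s),
            class = "kinetic_params")
}

#' Closed-form volume of distribution of a compartment model
#'
#' `K1/k2` for the one-tissue model and `(K1/k2) * (1 + k3/k4)` for the
#' reversible two-tissue model.
#'
#' @param params a [kinetic_params()] object.
#' @return VT in ml/g.
#' @export
analytic_vt <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$model == "one_tissue") params$K1 / params$k2
  else (params$K1 / params$k2) * (1 + params$k3 / params$k4)
}

# Impulse response of the tissue compartments as a sum of decaying
# exponentials, phi_m * exp(-theta_m * t), in per-second units.
.tissue_irf <- function(params) {
  K1 <- params$K1 / 60; k2 <- params$k2 / 60
  if (params$model == "one_tissue")
    return(list(phi = K1, theta = k2))
  k3 <- params$k3 / 60; k4 <- params$k4 / 60
  s <- k2 + k3 + k4
  p <- k2 * k4
  th1 <- (s + sqrt(s^2 - 4 * p)) / 2
  th2 <- (s - sqrt(s^2 - 4 * p)) / 2
  list(phi = c(K1 * (th1 - k3 - k4) / (th1 - th2),
               K1 * (k3 + k4 - th2) / (th1 - th2)),
       theta = c(th1, th2))
}

#' Simulate a frame-averaged tissue time-activity curve
#'
#' Convolves the input function with the analytic compartment impulse
#' response on a dense grid (0.5 s), composes the measured signal as
#' `(1 - vb) * tissue + vb * whole_blood`, averages over the acquisition
#' frames and adds zero-mean Gaussian noise whose per-frame variance is
#' proportional to `trues_rate / frame_dur` (the reciprocal of the
#' statistical frame weight) scaled by `noise_scale^2`. When the schedule
#' carries no trues rates they are synthesised as decay-weighted frame
#' activity, which makes relative noise grow over the scan as counts decay.
#'
#' @param input_function an `input_function`.
#' @param params a [kinetic_params()] ground truth.
#' @param schedule a [frame_schedule()].
#' @param noise_scale noise magnitude; 0 gives a noise-free curve.
#' @param seed integer seed for the noise draws.
#' @param whole_blood vascular curve (as in [build_basis()]); defaults to
#'   the blood dataset attached to the input function, then to the input
#'   function itself.
#' @return a `tissue_tac` data frame with attributes `truth` (the kinetic
#'   parameters and analytic VT) and `region`.
#' @export
gen_tissue_tac <- function(input_function, params, schedule,
                           noise_scale = 0, seed = NULL, whole_blood = NULL) {
  stopifnot(inherits(input_function, "input_function"),
            inherits(params, "kinetic_params"),
            inherits(schedule, "frame_schedule"))
  if (nrow(schedule) == 0L) .stopf("empty frame schedule")
  if (!is.null(seed)) set.seed(seed)
  dt <- 0.5
  t_end <- max(schedule$frame_start_s + schedule$frame_dur_s)
  shifted <- if (params$delay_s != 0) apply_delay(input_function, params$delay_s)
             else input_function
  u <- .dense_curve(shifted$time_s, shifted$parent_plasma_activity, t_end, dt)

  irf <- .tissue_irf(params)
  tissue <- Reduce(`+`, Map(function(phi, theta) phi * .exp_conv(u$v, dt, theta),
                            irf$phi, irf$theta))
  tissue_f <- .frame_average(tissue, dt, schedule)

  if (is.null(whole_blood)) whole_blood <- attr(input_function, "blood")
  if (is.null(whole_blood)) {
    wb_f <- .frame_average(.dense_curve(input_function$time_s,
                                        input_function$parent_plasma_activity,
                                        t_end, dt)$v, dt, schedule)
  } else if (inherits(whole_blood, "blood_dataset")) {
    wb_t <- c(whole_blood$continuous$time_s, whole_blood$discrete$time_min * 60)
    wb_v <- c(whole_blood$continuous$whole_blood, whole_blood$discrete$whole_blood)
    o <- order(wb_t); keep <- !duplicated(wb_t[o])
    wb_f <- .frame_average(.dense_curve(wb_t[o][keep], wb_v[o][keep], t_end, dt)$v,
                           dt, schedule)
  } else {
    wb_f <- .frame_average(.dense_curve(whole_blood$time_s,
                                        whole_blood[[2]], t_end, dt)$v,
                           dt, schedule)
  }

  signal <- (1 - params$vb) * tissue_f + params$vb * wb_f

  trues <- schedule$trues_rate
  if (any(is.na(trues))) {
    lambda <- decay_constant(20.4)
    trues <- pmax(signal, 1e-6) * exp(-lambda * schedule$frame_mid_s)
  }
  noise_sd <- noise_scale * sqrt(trues / schedule$frame_dur_s)
  activity <- signal + stats::rnorm(length(signal), 0, noise_sd)

  out <- data.frame(frame_start_s = schedule$frame_start_s,
                    frame_dur_s = schedule$frame_dur_s,
                    activity = activity,
                    trues_rate = trues)
  structure(out,
            truth = list(params = params, vt = analytic_vt(params),
                         noise_scale = noise_scale),
            region = "simulated",
            class = c("tissue_tac", "data.frame"))
}
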