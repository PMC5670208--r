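#' Specification of a synthetic study cohort
#'
#' Describes the drug/placebo crossover cohort the generators emulate:
#' subject count, the distribution of right-amygdala CB1 volume of
#' distribution (truncated normal: mean 12.57, SD 3.27, range 7.51-17.75
#' ml/g by default), and the target correlations between VT and the two
#' drug-effect outcomes (anxiety change and amygdala BOLD effect).
#'
#' @param n_subjects number of subjects (>= 3; default 14).
#' @param vt_mean,vt_sd VT distribution parameters in ml/g (`vt_sd > 0`).
#' @param vt_range truncation bounds in ml/g.
#' @param anxiety_effect_corr,ssq_effect_corr target Pearson correlations
#'   between VT and each outcome, in [-1, 1].
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 14, vt_mean = 12.57, vt_sd = 3.27,
                        vt_range = c(7.51, 17.75),
                        anxiety_effect_corr = 0.5, ssq_effect_corr = 0.5,
                        seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 3) .stopf("n_subjects must be >= 3")
  if (!is.finite(vt_sd) || vt_sd <= 0) .stopf("vt_sd must be > 0")
  if (length(vt_range) != 2L || vt_range[1] >= vt_range[2])
    .stopf("vt_range must be an increasing pair")
  for (r in c(anxiety_effect_corr, ssq_effect_corr))
    if (!is.finite(r) || abs(r) > 1) .stopf("correlations must lie in [-1, 1]")
  structure(list(n_subjects = as.integer(n_subjects), vt_mean = vt_mean,
                 vt_sd = vt_sd, vt_range = vt_range,
                 anxiety_effect_corr = anxiety_effect_corr,
                 ssq_effect_corr = ssq_effect_corr, seed = seed),
            class = "cohort_spec")
}

# mean and sd of a normal truncated to [lo, hi] (closed form)
.truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(v))
}

.rtruncnorm <- function(n, mu, sigma, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mu, sigma)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate subject-level records with known VT-outcome correlations
#'
#' Draws per-subject VT from the truncated normal in the [cohort_spec()],
#' then constructs the anxiety change (drug minus placebo 1-2 h window
#' mean, STAI-S units) and the amygdala BOLD (SSQ) effect with exactly the
#' requested Pearson correlations to VT: each outcome is
#' `rho * u + sqrt(1 - rho^2) * noise` where `u` is the analytically
#' standardised truncated-normal VT score. Post-hoc columns (PANSS-positive
#' change, fear-SCR count change) are generated uncorrelated.
#'
#' @param spec a [cohort_spec()].
#' @param anxiety_mean,anxiety_sd marginal moments of the anxiety change.
#' @param ssq_mean,ssq_sd marginal moments of the SSQ effect.
#' @return a `subject_records` data frame: `subject`,
#'   `vt_right_amygdala`, `anxiety_delta`, `ssq_effect`,
#'   `scr_fear_count_delta`, `psychosis_delta`.
#' @export
gen_cohort <- function(spec, anxiety_mean = 12, anxiety_sd = 7,
                       ssq_mean = 0.06, ssq_sd = 0.035) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  lo <- spec$vt_range[1]; hi <- spec$vt_range[2]
  vt <- .rtruncnorm(n, spec$vt_mean, spec$vt_sd, lo, hi)
  mo <- .truncnorm_moments(spec$vt_mean, spec$vt_sd, lo, hi)
  u <- (vt - mo$mean) / mo$sd

  mix <- function(rho) rho * u + sqrt(1 - rho^2) * stats::rnorm(n)
  anx <- anxiety_mean + anxiety_sd * mix(spec$anxiety_effect_corr)
  ssq <- ssq_mean + ssq_sd * mix(spec$ssq_effect_corr)

  out <- data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    vt_right_amygdala = vt,
    anxiety_delta = anx,
    ssq_effect = ssq,
    scr_fear_count_delta = round(stats::rnorm(n, 2, 3)),
    psychosis_delta = pmax(0, round(stats::rnorm(n, 3, 2)))
  )
  structure(out, class = c("subject_records", "data.frame"))
}

#' Generate a symptom ratings table for a crossover cohort
#'
#' Long-format psychopathological ratings (STAI-S state anxiety, Analogue
#' Intoxication Scale, PANSS positive/negative/total) per subject x
#' condition x time (0, 1, 2, 3 h post drug). Placebo series are constant
#' at each subject's baseline, reproducing the zero change-from-baseline
#' variance seen under placebo; drug series add a transient response
#' peaking between 1 and 2 h whose subject amplitude is right-skewed
#' (lognormal, sigma 0.25). The STAI-S amplitude is tied to the cohort's
#' VT draw so that the drug-minus-placebo 1-2 h anxiety change correlates
#' with VT at (almost exactly) the requested `anxiety_effect_corr`; the
#' mild lognormal skew attenuates the correlation by the analytic factor
#' sigma/sqrt(exp(sigma^2) - 1) = 0.984. STAI-S is bounded to [20, 80].
#'
#' @param spec a [cohort_spec()].
#' @param effect_scale multiplies every drug response amplitude; 0 makes
#'   drug identical to placebo.
#' @param seed overrides `spec$seed` for the rating draws.
#' @return a `ratings_table` data frame: `subject`, `condition`
#'   (`drug`/`placebo`), `scale`, `time_h`, `value`, with the generating
#'   `subject_records` attached as attribute `cohort`.
#' @export
gen_symptom_table <- function(spec, effect_scale = 1, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  cohort <- gen_cohort(spec)
  if (!is.null(seed)) set.seed(seed) else set.seed(spec$seed + 1L)
  n <- spec$n_subjects
  times <- c(0, 1, 2, 3)
  profile <- c(0, 0.9, 1, 0.45)           # transient peaking in the 1-2 h window
  win_gain <- mean(profile[times %in% c(1, 2)])

  mo <- .truncnorm_moments(spec$vt_mean, spec$vt_sd,
                           spec$vt_range[1], spec$vt_range[2])
  u <- (cohort$vt_right_amygdala - mo$mean) / mo$sd
  sig <- 0.25
  z_anx <- spec$anxiety_effect_corr * u +
    sqrt(1 - spec$anxiety_effect_corr^2) * stats::rnorm(n)
  # lognormal subject amplitude; scaled so the 1-2 h window change has a
  # ~12-point STAI-S mean at effect_scale = 1
  amp_stai <- 12 / win_gain * exp(sig * z_anx - sig^2 / 2) * effect_scale
  amp_ais <- 30 * exp(0.4 * stats::rnorm(n)) * effect_scale
  amp_pos <- 3 * exp(0.4 * stats::rnorm(n)) * effect_scale
  amp_neg <- 2 * exp(0.4 * stats::rnorm(n)) * effect_scale
  amp_tot <- amp_pos + amp_neg + 4 * exp(0.4 * stats::rnorm(n)) * effect_scale

  base <- list("STAI-S" = round(stats::runif(n, 24, 32)),
               "AIS" = rep(0, n),
               "PANSS-pos" = rep(7, n),
               "PANSS-neg" = rep(7, n),
               "PANSS-total" = rep(30, n))
  amps <- list("STAI-S" = amp_stai, "AIS" = amp_ais, "PANSS-pos" = amp_pos,
               "PANSS-neg" = amp_neg, "PANSS-total" = amp_tot)
  bounds <- list("STAI-S" = c(20, 80), "AIS" = c(0, 100),
                 "PANSS-pos" = c(7, 49), "PANSS-neg" = c(7, 49),
                 "PANSS-total" = c(30, 210))

  rows <- list()
  for (sc in names(base)) {
    for (cond in c("placebo", "drug")) {
      for (ti in seq_along(times)) {
        v <- base[[sc]] + if (cond == "drug") amps[[sc]] * profile[ti] else 0
        v <- pmin(pmax(v, bounds[[sc]][1]), bounds[[sc]][2])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = cohort$subject, condition = cond, scale = sc,
          time_h = times[ti], value = v)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$condition, out$scale, out$time_h), ]
  rownames(out) <- NULL
  structure(out, cohort = cohort, class = c("ratings_table", "data.frame"))
}
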