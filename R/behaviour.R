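#' Trapezoidal area under a rating time-course
#'
#' `sum over intervals of (v_i + v_{i+1}) / 2 * dt`; exact for
#' piecewise-linear series and additive over adjacent intervals.
#'
#' @param times_h strictly increasing times in hours (>= 2 points).
#' @param values ratings at those times.
#' @return AUC in scale-units x hours.
#' @examples
#' auc_trapezoid(c(0, 1, 2, 3), c(20, 40, 40, 20))  # 100
#' @export
auc_trapezoid <- function(times_h, values) {
  .check_finite(times_h, "times")
  .check_finite(values, "values")
  if (length(times_h) < 2L) .stopf("need at least 2 points")
  if (length(times_h) != length(values)) .stopf("length mismatch")
  .check_increasing(times_h, "times")
  sum(diff(times_h) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Friedman test for paired condition comparisons
#'
#' Non-parametric repeated-measures comparison across conditions using
#' within-subject mid-ranks with the standard tie correction:
#' `chi2 = [12 / (n k (k+1))] * sum(R_j^2) - 3 n (k+1)` (tie-adjusted),
#' `df = k - 1`. The asymptotic statistic and p come from
#' [stats::friedman.test()]; `exact = TRUE` replaces the p-value with the
#' exact conditional-permutation probability (all `k!^n` within-subject
#' rearrangements, feasible for small cohorts), which the asymptotic value
#' approximates.
#'
#' @param paired_matrix numeric matrix, subjects x conditions, no missing
#'   cells, >= 2 of each.
#' @param exact compute the exact permutation p-value (guarded to <= 2^20
#'   rearrangements).
#' @return list with `statistic` (chi-square), `df`, `p_value`, `n`, `k`,
#'   `method`.
#' @export
friedman_chi2 <- function(paired_matrix, exact = FALSE) {
  m <- as.matrix(paired_matrix)
  if (any(is.na(m))) .stopf("missing cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) .stopf("need >= 2 subjects and >= 2 conditions")
  ft <- stats::friedman.test(m)
  stat <- unname(ft$statistic)
  p <- unname(ft$p.value)
  method <- "asymptotic chi-square"

  if (exact) {
    n_arrange <- factorial(k)^n
    if (n_arrange > 2^20)
      .stopf("exact mode infeasible: %g rearrangements", n_arrange)
    perms <- .permutations(k)
    stat_of <- function(mm) unname(stats::friedman.test(mm)$statistic)
    # enumerate the product space of within-subject rearrangements
    idx <- rep(1L, n)
    count <- 0L; total <- 0L
    repeat {
      mm <- t(vapply(seq_len(n), function(i) m[i, perms[idx[i], ]], numeric(k)))
      total <- total + 1L
      if (stat_of(mm) >= stat - 1e-12) count <- count + 1L
      j <- 1L
      while (j <= n) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= nrow(perms)) break
        idx[j] <- 1L; j <- j + 1L
      }
      if (j > n) break
    }
    p <- count / total
    method <- "exact conditional permutation"
  }
  list(statistic = stat, df = k - 1L, p_value = p, n = n, k = k, method = method)
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Kolmogorov-Smirnov normality check for change scores
#'
#' One-sample KS test of the change-from-baseline values against a normal
#' distribution with the sample mean and SD (asymptotic p-value). A
#' zero-variance sample leaves the reference undefined and is an error.
#'
#' @param changes numeric vector, n >= 3.
#' @return list with `D`, `p_value`, `n`.
#' @export
ks_normality <- function(changes) {
  .check_finite(changes, "changes")
  if (length(changes) < 3L) .stopf("need n >= 3")
  if (stats::sd(changes) == 0) .stopf("zero-variance sample: test undefined")
  kt <- suppressWarnings(
    stats::ks.test(changes, "pnorm", mean(changes), stats::sd(changes),
                   exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value),
       n = length(changes))
}

#' Mean rating over the 1-2 h post-drug window
#'
#' The symptom measure used for correlational analyses: the imaging window
#' ran from one to two hours after drug administration, so the symptom
#' effect is the mean of the 1 h and 2 h ratings.
#'
#' @param times_h rating times in hours (must contain 1 and 2).
#' @param values ratings.
#' @return `(value at 1 h + value at 2 h) / 2`.
#' @export
window_mean_1_2h <- function(times_h, values) {
  if (length(times_h) != length(values)) .stopf("length mismatch")
  i1 <- which(times_h == 1); i2 <- which(times_h == 2)
  if (!length(i1) || !length(i2)) .stopf("ratings at 1 h and 2 h are required")
  (values[i1[1]] + values[i2[1]]) / 2
}

#' Per-scale symptom statistics for a crossover ratings table
#'
#' For every scale: the drug-versus-placebo Friedman test (on trapezoidal
#' AUCs by default, or on the per-timepoint values), the KS normality check
#' of the drug change from baseline at the 1-2 h window, and the mean
#' drug-minus-placebo window effect. No correction across scales is applied
#' by default, matching a within-but-not-across-hypotheses stance; set
#' `bonferroni = TRUE` to multiply p-values by the number of scales.
#'
#' @param ratings a `ratings_table` (long format: `subject`, `condition`,
#'   `scale`, `time_h`, `value`).
#' @param mode compare condition `"auc"`s (default) or stack the
#'   per-`"timepoint"` values.
#' @param baseline_subtract subtract each series' 0 h value before the AUC.
#' @param bonferroni apply a Bonferroni factor across scales.
#' @return data frame with one row per scale: `scale`, `friedman_chi2`,
#'   `df`, `p_value`, `ks_D`, `ks_p`, `mean_window_delta`.
#' @export
behaviour_stats <- function(ratings, mode = c("auc", "timepoint"),
                            baseline_subtract = FALSE, bonferroni = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(ratings),
            all(c("subject", "condition", "scale", "time_h", "value") %in% names(ratings)))
  scales <- unique(ratings$scale)
  res <- lapply(scales, function(sc) {
    r <- ratings[ratings$scale == sc, ]
    subjects <- unique(r$subject)
    per_subject <- function(fun) {
      vapply(c("drug", "placebo"), function(cond) {
        vapply(subjects, function(s) {
          x <- r[r$subject == s & r$condition == cond, ]
          x <- x[order(x$time_h), ]
          fun(x$time_h, x$value)
        }, numeric(1))
      }, numeric(length(subjects)))
    }
    if (mode == "auc") {
      m <- per_subject(function(t, v) {
        if (baseline_subtract) v <- v - v[1]
        auc_trapezoid(t, v)
      })
    } else {
      m <- NULL
      for (th in sort(unique(r$time_h)))
        m <- rbind(m, per_subject(function(t, v) v[t == th]))
    }
    fr <- friedman_chi2(m)
    wdelta <- per_subject(function(t, v) window_mean_1_2h(t, v))
    eff <- wdelta[, "drug"] - wdelta[, "placebo"]
    changes <- per_subject(function(t, v) window_mean_1_2h(t, v) - v[t == 0])[, "drug"]
    ks <- tryCatch(ks_normality(changes),
                   error = function(e) list(D = NA_real_, p_value = NA_real_))
    data.frame(scale = sc, friedman_chi2 = fr$statistic, df = fr$df,
               p_value = fr$p_value, ks_D = ks$D, ks_p = ks$p_value,
               mean_window_delta = mean(eff))
  })
  out <- do.call(rbind, res)
  if (bonferroni) out$p_value <- pmin(1, out$p_value * length(scales))
  rownames(out) <- NULL
  out
}
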