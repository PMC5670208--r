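#' Mean statistic over a cluster mask
#'
#' Extracts the per-subject effect measure for the correlation stage: the
#' mean of an SSQ (or any) map over the voxels of a cluster mask.
#'
#' @param map 3-D numeric array.
#' @param mask logical array on the same grid with at least one voxel.
#' @return mean map value over the mask.
#' @export
extract_cluster_mean <- function(map, mask) {
  if (!identical(dim(map), dim(mask))) .stopf("map and mask grids differ")
  mask <- as.logical(mask)
  if (!any(mask)) .stopf("empty cluster mask")
  mean(map[mask])
}

#' Pearson product-moment correlation with t-based p-value
#'
#' `r` with `p` from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom (via [stats::cor.test()]). One-sided tests are
#' directional for positive association; for positive `r` the one-sided p
#' is exactly half the two-sided p.
#'
#' @param x,y numeric vectors, n >= 3, both with non-zero variance.
#' @param sidedness `"two"` (default) or `"one"`.
#' @return list with `r`, `p_value`, `n`, `t`, `df`, `at_floor` (TRUE when
#'   the correlation is numerically perfect and p sits at the floor).
#' @export
pearson_corr <- function(x, y, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  .check_finite(x, "x"); .check_finite(y, "y")
  if (length(x) != length(y)) .stopf("length mismatch")
  n <- length(x)
  if (n < 3L) .stopf("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) .stopf("zero variance input")
  alt <- if (sidedness == "two") "two.sided" else "greater"
  ct <- stats::cor.test(x, y, method = "pearson", alternative = alt)
  r <- unname(ct$estimate)
  p <- unname(ct$p.value)
  at_floor <- abs(r) >= 1 - 1e-12
  if (at_floor) p <- max(p, .Machine$double.xmin)
  list(r = r, p_value = p, n = n, t = unname(ct$statistic),
       df = unname(ct$parameter), at_floor = at_floor)
}

#' Relate regional VT to the drug-effect measures
#'
#' The correlation stage: Pearson correlations of right-amygdala VT with
#' the drug-induced anxiety change and with the amygdala BOLD (SSQ) effect
#' (the two primary, hypothesis-driven tests), plus the post-hoc checks
#' (VT versus psychotic-symptom change; SSQ effect versus fear-SCR count
#' change). No multiplicity correction is applied across hypotheses --
#' they are deliberately few and not independent -- and every row reports
#' n, r and both one- and two-sided p-values.
#'
#' @param records a `subject_records` data frame (see [gen_cohort()]) with
#'   complete `vt_right_amygdala`, `anxiety_delta`, `ssq_effect`,
#'   `scr_fear_count_delta`, `psychosis_delta` columns.
#' @param hypotheses optional data frame (`x`, `y`, `role`) overriding the
#'   default four tests.
#' @return an `association_report` data frame: `hypothesis`, `role`, `n`,
#'   `r`, `t`, `p_two_sided`, `p_one_sided`, `at_floor`.
#' @export
run_association <- function(records, hypotheses = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(hypotheses)) {
    hypotheses <- data.frame(
      x = c("vt_right_amygdala", "vt_right_amygdala",
            "vt_right_amygdala", "ssq_effect"),
      y = c("anxiety_delta", "ssq_effect",
            "psychosis_delta", "scr_fear_count_delta"),
      role = c("primary", "primary", "post-hoc", "post-hoc")
    )
  }
  need <- unique(c(hypotheses$x, hypotheses$y))
  miss <- setdiff(need, names(records))
  if (length(miss)) .stopf("records lack field(s): %s", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(records[, need])
  if (sum(cc) < 3L) .stopf("need >= 3 complete records")
  records <- records[cc, ]

  rows <- lapply(seq_len(nrow(hypotheses)), function(i) {
    x <- records[[hypotheses$x[i]]]
    y <- records[[hypotheses$y[i]]]
    two <- pearson_corr(x, y, "two")
    one <- pearson_corr(x, y, "one")
    data.frame(hypothesis = sprintf("%s ~ %s", hypotheses$y[i], hypotheses$x[i]),
               role = hypotheses$role[i], n = two$n, r = two$r, t = two$t,
               p_two_sided = two$p_value, p_one_sided = one$p_value,
               at_floor = two$at_floor)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("association_report", "data.frame"))
}

#' @export
print.association_report <- function(x, ...) {
  cat("Association report (no cross-hypothesis multiplicity correction)\n")
  df <- as.data.frame(x)
  df$r <- round(df$r, 3)
  df$p_two_sided <- signif(df$p_two_sided, 3)
  df$p_one_sided <- signif(df$p_one_sided, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
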