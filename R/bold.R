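#' Two-gamma haemodynamic regressors for an event-related design
#'
#' Convolves the experimental event train with two gamma-variate kernels of
#' distinct peak latencies (defaults 4 s and 8 s, unit-peak normalised) to
#' model the BOLD response, and samples the result at the volume times. The
#' event train carries the condition contrast (+1 fearful, -1 neutral by
#' default); the weighted sum of the two resulting regressors is the
#' constrained BOLD effects model fitted by [fit_ssq()].
#'
#' @param onsets event onset times in seconds, within the run.
#' @param labels condition label per event (names of `contrast`).
#' @param tr repetition time in seconds (> 0).
#' @param n_volumes number of acquired volumes.
#' @param contrast named contrast weights per condition.
#' @param peaks kernel peak latencies in seconds.
#' @param shape gamma shape parameter (scale set so the mode hits each
#'   peak).
#' @param duration event duration in seconds (0 = impulse).
#' @param dt internal convolution grid step, seconds.
#' @return matrix `n_volumes` x `length(peaks)` of regressors.
#' @export
gamma_hrf_regressors <- function(onsets, labels, tr, n_volumes,
                                 contrast = c(fearful = 1, neutral = -1),
                                 peaks = c(4, 8), shape = 6,
                                 duration = 0, dt = 0.1) {
  if (!is.finite(tr) || tr <= 0) .stopf("TR must be > 0")
  run_len <- n_volumes * tr
  if (length(onsets)) {
    .check_finite(onsets, "onsets")
    if (any(onsets < 0 | onsets >= run_len)) .stopf("event onset outside the run")
    if (length(labels) != length(onsets)) .stopf("one label per onset required")
    if (!all(labels %in% names(contrast)))
      .stopf("labels must match the contrast names")
  }
  kernel_support <- max(peaks) * 5
  if (kernel_support > run_len)
    .stopf("kernel support (%.0f s) exceeds the run length (%.0f s)",
           kernel_support, run_len)

  t_grid <- seq(0, run_len, by = dt)
  train <- numeric(length(t_grid))
  for (i in seq_along(onsets)) {
    w <- contrast[[labels[i]]]
    if (duration > 0) {
      sel <- t_grid >= onsets[i] & t_grid < onsets[i] + duration
      train[sel] <- train[sel] + w
    } else {
      train[round(onsets[i] / dt) + 1L] <- train[round(onsets[i] / dt) + 1L] + w
    }
  }

  t_vol <- (seq_len(n_volumes) - 1) * tr
  out <- vapply(peaks, function(pk) {
    theta <- pk / (shape - 1)
    h <- t_grid^(shape - 1) * exp(-t_grid / theta)
    h <- h / max(h)
    conv <- stats::convolve(train, rev(h), type = "open")[seq_along(t_grid)]
    conv[round(t_vol / dt) + 1L]
  }, numeric(n_volumes))
  colnames(out) <- sprintf("hrf_peak%gs", peaks)
  out
}

#' Fit the constrained BOLD effects model and form the SSQ ratio
#'
#' Least-squares fit of a weighted sum of the haemodynamic regressors to a
#' (de-meaned) voxel time series. The effect statistic is the sum-of-squares
#' ratio `SSQ = model SS / residual SS`. The "constrained" element requires
#' the fitted combined response to be non-negative at its peak: if the
#' best-fitting response is everywhere non-positive the constraint binds and
#' the fit collapses to zero (flagged). A residual of (numerically) zero is
#' reported at the cap with `capped = TRUE`.
#'
#' @param timeseries numeric voxel time series.
#' @param regressors matrix from [gamma_hrf_regressors()] (rows =
#'   timepoints).
#' @param constrain apply the peak non-negativity constraint (default TRUE).
#' @param cap value reported when the residual vanishes.
#' @return an `ssq_fit`: list with `weights`, `ssq_ratio`, `model_ss`,
#'   `residual_ss`, `capped`, `constraint_active`.
#' @export
fit_ssq <- function(timeseries, regressors, constrain = TRUE, cap = 1e6) {
  y <- as.numeric(timeseries)
  X <- as.matrix(regressors)
  if (length(y) != nrow(X)) .stopf("time series and regressors differ in length")
  .check_finite(y, "time series")
  y <- y - mean(y)
  X <- sweep(X, 2, colMeans(X))
  tot <- sum(y^2)
  zero_fit <- function(active) {
    structure(list(weights = rep(0, ncol(X)), ssq_ratio = 0,
                   model_ss = 0, residual_ss = tot, capped = FALSE,
                   constraint_active = active), class = "ssq_fit")
  }
  if (tot == 0 || all(abs(X) < .Machine$double.eps)) return(zero_fit(FALSE))

  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  beta[is.na(beta)] <- 0
  fitted <- as.numeric(X %*% beta)
  if (constrain && max(fitted) < 0) return(zero_fit(TRUE))

  model_ss <- sum(fitted^2)
  resid_ss <- sum((y - fitted)^2)
  capped <- resid_ss <= tot * 1e-12
  ratio <- if (capped) cap else model_ss / resid_ss
  structure(list(weights = beta, ssq_ratio = ratio, model_ss = model_ss,
                 residual_ss = resid_ss, capped = capped,
                 constraint_active = FALSE), class = "ssq_fit")
}

#' Permutation p-value for a voxel's SSQ ratio
#'
#' Compares the observed SSQ ratio with its distribution under permutations
#' that break the stimulus-response alignment while preserving the series'
#' autocorrelation structure: circular time shifts (default) or coarse
#' block permutation. `p = (1 + #[permuted >= observed]) / (n_perm + 1)`,
#' which is valid (sub-uniform under the null) by construction.
#'
#' @inheritParams fit_ssq
#' @param n_perm number of permutations (>= 100).
#' @param scheme `"circular_shift"` or `"block_permute"`.
#' @param seed integer seed.
#' @param block_len block length in volumes for `"block_permute"`.
#' @return list with `p_value`, `observed`, `n_perm`.
#' @export
permutation_p <- function(timeseries, regressors, n_perm = 500,
                          scheme = c("circular_shift", "block_permute"),
                          seed = NULL, block_len = 10, constrain = TRUE) {
  scheme <- match.arg(scheme)
  if (n_perm < 100) .stopf("n_perm must be >= 100")
  y <- as.numeric(timeseries)
  n <- length(y)
  if (stats::sd(y) == 0) .stopf("degenerate (constant) time series")
  if (!is.null(seed)) set.seed(seed)
  obs <- fit_ssq(y, regressors, constrain = constrain)$ssq_ratio

  X <- sweep(as.matrix(regressors), 2, colMeans(as.matrix(regressors)))
  Q <- qr.Q(qr(X))
  yc <- y - mean(y)

  Yp <- matrix(0, n, n_perm)
  if (scheme == "circular_shift") {
    shifts <- sample.int(n - 1L, n_perm, replace = TRUE)
    for (r in seq_len(n_perm)) {
      s <- shifts[r]
      Yp[, r] <- yc[c((s + 1L):n, 1L:s)]
    }
  } else {
    n_blocks <- ceiling(n / block_len)
    block_of <- rep(seq_len(n_blocks), each = block_len)[seq_len(n)]
    for (r in seq_len(n_perm)) {
      ord <- sample(n_blocks)
      idx <- unlist(lapply(ord, function(b) which(block_of == b)))
      Yp[, r] <- yc[idx]
    }
  }

  P <- crossprod(Q, Yp)
  model_ss <- colSums(P^2)
  tot <- colSums(Yp^2)
  resid_ss <- pmax(tot - model_ss, 0)
  ratio <- ifelse(resid_ss <= tot * 1e-12, 1e6, model_ss / resid_ss)
  if (constrain) {
    Fhat <- Q %*% P
    ratio[apply(Fhat, 2, max) < 0] <- 0
  }
  list(p_value = (1 + sum(ratio >= obs)) / (n_perm + 1),
       observed = obs, n_perm = n_perm)
}
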