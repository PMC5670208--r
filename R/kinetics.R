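# Convolution of a sampled curve u(t) (uniform grid, step dt, starting at 0)
# with exp(-beta * t), evaluated on the same grid. Exact for piecewise-linear
# u: each step carries the closed-form segment integral and the recursion
# C_k = E * C_{k-1} + s_k is run at C level through stats::filter().
.exp_conv <- function(u, dt, beta) {
  n <- length(u)
  if (beta * dt < 1e-12) {           # beta -> 0 limit: running integral of u
    seg <- (u[-n] + u[-1]) / 2 * dt
    return(c(0, cumsum(seg)))
  }
  E <- exp(-beta * dt)
  a <- u[-n]
  b <- u[-1]
  w1 <- (1 - E) / beta
  seg <- a * w1 + (b - a) * (dt - w1) / (beta * dt)
  c(0, as.numeric(stats::filter(seg, E, method = "recursive")))
}

# Frame averages of a dense curve sampled at 0, dt, 2*dt, ... : mean of the
# trapezoid integral over each frame divided by the frame length. Frame
# boundaries must fall on the dense grid.
.frame_average <- function(x, dt, schedule) {
  n <- length(x)
  ct <- c(0, cumsum((x[-n] + x[-1]) / 2 * dt))
  i0 <- round(schedule$frame_start_s / dt) + 1L
  i1 <- round((schedule$frame_start_s + schedule$frame_dur_s) / dt) + 1L
  if (any(i1 > n)) .stopf("curve does not cover the frame schedule")
  (ct[i1] - ct[i0]) / schedule$frame_dur_s
}

# Dense resampling of an input function or of a whole-blood curve over the
# scan, with exponential tail extrapolation past the last breakpoint.
.dense_curve <- function(time_s, value, t_end, dt) {
  t_dense <- seq(0, t_end, by = dt)
  v <- .extend_curve(time_s, value, t_dense)
  v[v < 0] <- 0
  list(t = t_dense, v = v)
}

#' Build the spectral basis for a frame schedule
#'
#' Spectral analysis models a tissue time-activity curve as a non-negative
#' sum of convolutions of the input function with decaying exponentials
#' `exp(-beta_j t)`. This function evaluates those convolutions on a dense
#' internal grid (step `dt` <= 1 s), averages them over the acquisition
#' frames, and appends a frame-averaged whole-blood column for the vascular
#' (blood volume) term. The frequency grid is log-spaced between `beta_slow`
#' and `beta_fast`; the defaults are 0.00063 s^-1 (just above the carbon-11
#' decay constant 0.0005663 s^-1, since nothing in tissue can appear slower
#' than the physical decay of the label) and 0.1 s^-1.
#'
#' @param input_function an `input_function` (see
#'   [apply_parent_correction()]).
#' @param schedule a [frame_schedule()].
#' @param beta_slow,beta_fast frequency bounds in s^-1, `beta_slow <
#'   beta_fast`.
#' @param n_beta number of grid points (>= 2; default 100).
#' @param dt internal grid step in seconds (<= 1).
#' @param whole_blood optional whole-blood curve for the vascular column: a
#'   `blood_dataset`, or a data frame with `time_s` and an activity column.
#'   Defaults to the blood dataset attached to the input function, falling
#'   back (with a message) to the input function itself.
#' @return a `spectral_basis`: list with `beta`, `basis` (frames x n_beta),
#'   `blood` (frame-averaged vascular column), `schedule`, `dt`.
#' @export
build_basis <- function(input_function, schedule,
                        beta_slow = 0.00063, beta_fast = 0.1,
                        n_beta = 100, dt = 1, whole_blood = NULL) {
  stopifnot(inherits(input_function, "input_function"),
            inherits(schedule, "frame_schedule"))
  if (!is.finite(beta_slow) || !is.finite(beta_fast) || beta_slow <= 0 ||
      beta_slow >= beta_fast)
    .stopf("need 0 < beta_slow < beta_fast")
  if (n_beta < 2L) .stopf("n_beta must be >= 2")
  if (dt > 1) .stopf("internal grid step dt must be <= 1 s")

  t_end <- max(schedule$frame_start_s + schedule$frame_dur_s)
  u <- .dense_curve(input_function$time_s, input_function$parent_plasma_activity,
                    t_end, dt)
  beta <- exp(seq(log(beta_slow), log(beta_fast), length.out = n_beta))
  B <- vapply(beta, function(b) .frame_average(.exp_conv(u$v, dt, b), dt, schedule),
              numeric(nrow(schedule)))

  if (is.null(whole_blood)) whole_blood <- attr(input_function, "blood")
  if (is.null(whole_blood)) {
    message("no whole-blood curve available; using the input function as vascular column")
    blood_col <- .frame_average(u$v, dt, schedule)
  } else {
    if (inherits(whole_blood, "blood_dataset")) {
      wb_t <- c(whole_blood$continuous$time_s, whole_blood$discrete$time_min * 60)
      wb_v <- c(whole_blood$continuous$whole_blood, whole_blood$discrete$whole_blood)
      o <- order(wb_t)
      keep <- !duplicated(wb_t[o])
      wb_t <- wb_t[o][keep]; wb_v <- wb_v[o][keep]
    } else {
      wb_t <- whole_blood$time_s
      wb_v <- whole_blood[[setdiff(names(whole_blood), "time_s")[1]]]
    }
    wb <- .dense_curve(wb_t, wb_v, t_end, dt)
    blood_col <- .frame_average(wb$v, dt, schedule)
  }

  structure(list(beta = beta, basis = B, blood = blood_col,
                 schedule = schedule, dt = dt),
            class = "spectral_basis")
}

#' Weighted non-negative least squares
#'
#' Solves `min || sqrt(w) * (y - A x) ||^2` subject to `x >= 0` with the
#' Lawson-Hanson algorithm. This is the work-horse behind [fit_spectral()];
#' it is exported so the solution can be cross-checked against independent
#' quadratic-programming solvers.
#'
#' @param A design matrix (frames x components).
#' @param y response vector.
#' @param w non-negative weights (default uniform).
#' @return list with `x` (coefficients) and `rss` (weighted residual sum of
#'   squares).
#' @export
spectral_nnls <- function(A, y, w = rep(1, length(y))) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  if (nrow(A) != length(y) || length(w) != length(y))
    .stopf("dimension mismatch in spectral_nnls")
  if (any(w < 0)) .stopf("negative weights")
  sw <- sqrt(w)
  # pracma's Lawson-Hanson caps its cumulative inner iterations at 3n, which
  # near-collinear many-column bases can exceed on noisy data; fall back to
  # the package's own implementation with a generous budget in that case
  sol <- tryCatch(pracma::lsqnonneg(sw * A, sw * y), error = function(e) NULL)
  if (is.null(sol)) {
    x <- .nnls_lawson_hanson(sw * A, sw * y)
    return(list(x = x, rss = sum((sw * y - (sw * A) %*% x)^2)))
  }
  list(x = sol$x, rss = sol$resid.norm)
}

# Lawson-Hanson active-set NNLS with a large iteration budget. Used only
# when the primary solver exhausts its fixed iteration cap.
.nnls_lawson_hanson <- function(A, y, itmax = NULL) {
  n <- ncol(A)
  if (is.null(itmax)) itmax <- 100L * n
  tol <- 10 * .Machine$double.eps * norm(A, "2") * (max(dim(A)) + 1)
  x <- numeric(n)
  P <- logical(n)
  it <- 0L
  repeat {
    wgrad <- crossprod(A, y - A %*% x)
    free <- !P & wgrad > tol
    if (!any(free)) break
    P[which.max(replace(as.numeric(wgrad), P | wgrad <= tol, -Inf))] <- TRUE
    repeat {
      z <- numeric(n)
      z[P] <- qr.solve(A[, P, drop = FALSE], y)
      if (all(z[P] > 0)) break
      it <- it + 1L
      if (it > itmax) {
        .warnf("NNLS fallback iteration budget exhausted; returning best iterate")
        return(pmax(x, 0))
      }
      Q <- P & z <= 0
      alpha <- min(x[Q] / (x[Q] - z[Q]))
      x <- x + alpha * (z - x)
      P <- P & abs(x) >= tol
    }
    x <- z
    it <- it + 1L
    if (it > itmax) {
      .warnf("NNLS fallback iteration budget exhausted; returning best iterate")
      return(pmax(x, 0))
    }
  }
  x
}

# Gaussian smoothing of the coefficient spectrum along the log-beta grid,
# preserving total coefficient mass. A variance-control filter for slowly
# equilibrating tracers, applied optionally after the NNLS estimate.
.shape_spectrum <- function(alpha, sd_steps = 2) {
  n <- length(alpha)
  if (sd_steps <= 0 || sum(alpha) == 0) return(alpha)
  K <- outer(seq_len(n), seq_len(n),
             function(i, j) stats::dnorm(i - j, sd = sd_steps))
  K <- K / rowSums(K)
  out <- as.numeric(K %*% alpha)
  out * sum(alpha) / sum(out)
}

#' Fit a tissue time-activity curve by spectral analysis
#'
#' Minimises the weighted residual `sum_i w_i (tac_i - model_i)^2` with
#' `model = (1 - Vb) * basis %*% alpha + Vb * blood`, subject to
#' `alpha_j >= 0` and `0 <= Vb <= 1`. Coefficients are found by non-negative
#' least squares at each candidate blood-volume fraction (coarse grid plus
#' golden-section refinement, or a fixed value via `vb`). The summary
#' measures are the volume of distribution `VT = sum(alpha / beta)` --- the
#' equilibrium tissue-to-plasma concentration ratio, reported in ml/g
#' assuming unit tissue density --- and the impulse response function at 60
#' min, `sum(alpha * exp(-beta * 3600))`.
#'
#' @param tac a `tissue_tac` or a numeric activity vector (one value per
#'   frame).
#' @param basis a `spectral_basis` from [build_basis()].
#' @param weights frame weights (see [frame_weights()]); default uniform
#'   with a message.
#' @param regularisation `"none"` (plain spectral analysis, the default) or
#'   `"rank_shaping"`, a mass-preserving Gaussian filter of width `rs_sd`
#'   grid steps applied to the coefficient spectrum to control its variance.
#' @param vb `NULL` to estimate the blood-volume fraction, or a fixed value
#'   in [0, 1].
#' @param rs_sd filter width (log-grid steps) for `"rank_shaping"`.
#' @return a `spectral_fit`: list with `alpha`, `beta`, `vb`, `vt`,
#'   `irf_60min`, `weighted_rss`, `fitted`.
#' @export
fit_spectral <- function(tac, basis, weights = NULL,
                         regularisation = c("none", "rank_shaping"),
                         vb = NULL, rs_sd = 2) {
  regularisation <- match.arg(regularisation)
  stopifnot(inherits(basis, "spectral_basis"))
  y <- if (is.data.frame(tac)) tac$activity else as.numeric(tac)
  .check_finite(y, "tissue activity")
  nf <- nrow(basis$basis)
  if (length(y) != nf) .stopf("TAC has %d frames, basis %d", length(y), nf)
  if (is.null(weights)) {
    message("no frame weights supplied; using uniform weights")
    weights <- rep(1, nf)
  }
  if (length(weights) != nf) .stopf("weights length mismatch")
  if (any(weights < 0)) .stopf("negative weights")
  if (all(weights == 0)) .stopf("all frame weights are zero")
  if (any(colSums(abs(basis$basis)) == 0))
    .warnf("spectral basis contains an all-zero column (degenerate input function)")

  sw <- sqrt(weights)
  obj <- function(v) {
    if (v >= 1) {
      resid <- y - basis$blood
      return(list(alpha = rep(0, length(basis$beta)),
                  rss = sum(weights * resid^2)))
    }
    sol <- spectral_nnls((1 - v) * basis$basis, y - v * basis$blood, weights)
    list(alpha = sol$x, rss = sol$rss)
  }

  if (!is.null(vb)) {
    if (vb < 0 || vb > 1) .stopf("vb must lie in [0, 1]")
    best_v <- vb
  } else {
    grid <- seq(0, 1, by = 0.05)
    rss_grid <- vapply(grid, function(v) obj(v)$rss, numeric(1))
    i <- which.min(rss_grid)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    best_v <- if (lo == hi) lo else
      stats::optimize(function(v) obj(v)$rss, c(lo, hi), tol = 1e-4)$minimum
    if (rss_grid[i] <= obj(best_v)$rss) best_v <- grid[i]
  }
  sol <- obj(best_v)
  alpha <- sol$alpha
  if (regularisation == "rank_shaping") alpha <- .shape_spectrum(alpha, rs_sd)
  fitted <- as.numeric((1 - best_v) * basis$basis %*% alpha + best_v * basis$blood)

  structure(list(
    alpha = alpha,
    beta = basis$beta,
    vb = best_v,
    vt = sum(alpha / basis$beta),
    irf_60min = sum(alpha * exp(-basis$beta * 3600)),
    weighted_rss = sum(weights * (y - fitted)^2),
    fitted = fitted,
    regularisation = regularisation,
    units = "ml/g (tissue density 1 g/ml assumed)"
  ), class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat("spectral_fit\n")
  cat(sprintf("  VT = %.4g %s, Vb = %.3f, IRF(60 min) = %.4g 1/s\n",
              x$vt, "ml/g", x$vb, x$irf_60min))
  cat(sprintf("  %d basis frequencies in [%.3g, %.3g] 1/s, %d non-zero, weighted rss %.4g\n",
              length(x$beta), min(x$beta), max(x$beta), sum(x$alpha > 0),
              x$weighted_rss))
  invisible(x)
}

#' @export
plot.spectral_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(log10(x$beta), x$alpha, type = "h",
                 xlab = "log10 beta (1/s)", ylab = "alpha (1/s)",
                 main = "coefficient spectrum", ...)
  graphics::plot(x$fitted, type = "b", xlab = "frame", ylab = "activity",
                 main = sprintf("fit, VT = %.3g", x$vt))
  invisible(x)
}

#' Mean regional time-activity curve from a dynamic image
#'
#' Unweighted mean over all voxels carrying `label` in an integer label map,
#' for each frame of a 4-D dynamic image. Accepts in-memory arrays, or NIfTI
#' file paths when the RNifti package is installed.
#'
#' @param dynamic_image 4-D numeric array (x, y, z, frame) or a NIfTI path.
#' @param label_map 3-D integer array on the same grid, or a NIfTI path.
#' @param label the region label to average.
#' @param schedule optional [frame_schedule()]; when supplied the result is
#'   a `tissue_tac` data frame, otherwise a plain activity vector.
#' @param region region name recorded in the output.
#' @return `tissue_tac` data frame (`frame_start_s`, `frame_dur_s`,
#'   `activity`, `trues_rate`) or numeric vector.
#' @export
roi_mean_tac <- function(dynamic_image, label_map, label, schedule = NULL,
                         region = as.character(label)) {
  read_nifti <- function(p) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      .stopf("reading NIfTI paths requires the RNifti package")
    as.array(RNifti::readNifti(p))
  }
  if (is.character(dynamic_image)) dynamic_image <- read_nifti(dynamic_image)
  if (is.character(label_map)) label_map <- read_nifti(label_map)
  dims <- dim(dynamic_image)
  if (length(dims) != 4L) .stopf("dynamic image must be 4-D (x, y, z, frame)")
  if (!identical(dim(label_map), dims[1:3]))
    .stopf("label map grid does not match the dynamic image")
  idx <- which(label_map == label)
  if (!length(idx)) .stopf("label %s absent from the label map", format(label))
  mat <- matrix(dynamic_image, nrow = prod(dims[1:3]), ncol = dims[4])
  tac <- colMeans(mat[idx, , drop = FALSE])
  if (is.null(schedule)) return(tac)
  stopifnot(inherits(schedule, "frame_schedule"), nrow(schedule) == dims[4])
  out <- data.frame(frame_start_s = schedule$frame_start_s,
                    frame_dur_s = schedule$frame_dur_s,
                    activity = tac,
                    trues_rate = schedule$trues_rate)
  structure(out, region = region, class = c("tissue_tac", "data.frame"))
}
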