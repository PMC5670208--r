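#' @keywords internal
"_PACKAGE"

# Internal input-checking helpers. Kept deliberately tiny: every exported
# function validates its own contract and fails early with a clear message.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    .stopf("%s must be finite numeric", what)
  invisible(x)
}

.check_increasing <- function(x, what, strict = TRUE) {
  d <- diff(x)
  if ((strict && any(d <= 0)) || (!strict && any(d < 0)))
    .stopf("%s must be %s increasing", what, if (strict) "strictly" else "monotonically")
  invisible(x)
}

#' Four-parameter logistic (sigmoid) curve
#'
#' `a + (b - a) / (1 + (t / c)^d)`: `b` is the value at `t = 0`, `a` the
#' plateau as `t` grows, `c` the half-transition point (same units as `t`)
#' and `d` the steepness. Used for the plasma-to-blood ratio and the parent
#' (unmetabolised tracer) fraction, both of which are smooth monotone
#' functions of time after injection.
#'
#' @param t times (non-negative).
#' @param a,b,c,d curve parameters; `c > 0` required.
#' @return numeric vector of curve values.
#' @export
logistic4 <- function(t, a, b, c, d) {
  if (!is.finite(c) || c <= 0) .stopf("logistic4: c must be > 0")
  r <- (t / c)^d
  r[t == 0] <- if (d > 0) 0 else Inf
  a + (b - a) / (1 + r)
}

# Linear interpolation inside the observed range, single-exponential
# (log-linear) extrapolation beyond the last breakpoint, zero before the
# first. Blood curves end before the scan does, so the tail matters.
.extend_curve <- function(time, value, t_out) {
  stopifnot(length(time) == length(value), length(time) >= 2)
  keep <- !duplicated(time)
  time <- time[keep]
  value <- value[keep]
  out <- stats::approx(time, value, xout = t_out, rule = 1)$y
  out[t_out < time[1]] <- 0
  beyond <- t_out > time[length(time)]
  if (any(beyond)) {
    k <- length(time)
    i <- max(1, k - 2):k
    v <- value[i]
    if (all(v > 0) && stats::sd(log(v)) > 0) {
      fit <- stats::lm.fit(cbind(1, time[i]), log(v))
      out[beyond] <- exp(fit$coefficients[1] + fit$coefficients[2] * t_out[beyond])
    } else {
      out[beyond] <- value[k]
    }
  }
  out
}

# Row medians of a numeric matrix via one radix sort; fast enough for
# permutation loops over ~10^4-voxel volumes without compiled code.
.row_medians <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  if (k == 1L) return(x[, 1L])
  xs <- matrix(x[order(row(x), x)], nrow = n, byrow = TRUE)
  if (k %% 2L == 0L) (xs[, k %/% 2L] + xs[, k %/% 2L + 1L]) / 2 else xs[, (k + 1L) %/% 2L]
}

# Row-wise empirical quantile (type 1, right tail) of |x|; used for
# voxelwise permutation thresholds.
.row_abs_quantile <- function(x, prob) {
  n <- nrow(x)
  k <- ncol(x)
  a <- abs(x)
  xs <- matrix(a[order(row(a), a)], nrow = n, byrow = TRUE)
  xs[, max(1L, ceiling(prob * k))]
}
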