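#' Fit a four-parameter sigmoid to timed measurements
#'
#' Least-squares fit of the [logistic4()] model, used for the plasma-to-blood
#' ratio (fitted on the first six discrete arterial samples) and for the
#' parent fraction (fitted on the eight metabolite measurements). The fit is
#' multi-start: a small grid of half-point and steepness initialisations is
#' tried with a Levenberg-Marquardt optimiser and the lowest residual sum of
#' squares wins, making the result invariant to the ordering of the points.
#'
#' @param times sample times (same unit as later predictions; minutes for
#'   blood work), >= 0.
#' @param values measured values, finite, same length as `times`.
#' @param n_starts number of initialisations kept from the start grid
#'   (default 8, minimum 5).
#' @param on_fail `"error"` (default) signals if no start converges;
#'   `"best"` returns the best non-converged candidate with a warning.
#' @return a `sigmoid_model`: list with `par` (a, b, c, d), `rss`,
#'   `converged`, `n`. Evaluate it with `predict()`.
#' @examples
#' t <- c(3, 5, 10, 15, 20, 30)
#' y <- logistic4(t, a = 0.6, b = 1.4, c = 10, d = 3)
#' fit <- fit_sigmoid(t, y)
#' predict(fit, t)
#' @export
fit_sigmoid <- function(times, values, n_starts = 8, on_fail = c("error", "best")) {
  on_fail <- match.arg(on_fail)
  .check_finite(times, "times")
  .check_finite(values, "values")
  if (length(times) != length(values)) .stopf("times and values differ in length")
  if (length(times) < 5L)
    .stopf("need at least 5 points to fit 4 parameters (got %d)", length(times))
  o <- order(times)
  times <- times[o]
  values <- values[o]

  new_model <- function(par, rss, converged) {
    structure(list(par = par, rss = rss, converged = converged,
                   n = length(times)),
              class = "sigmoid_model")
  }

  if (stats::sd(values) == 0) {
    v <- values[1]
    return(new_model(c(a = v, b = v, c = max(stats::median(times), 1e-6), d = 1),
                     rss = 0, converged = TRUE))
  }

  tp <- times[times > 0]
  c_grid <- unique(pmax(stats::quantile(tp, c(0.25, 0.5, 0.75), names = FALSE), 1e-3))
  d_grid <- c(0.5, 1, 2, 4, 8)
  starts <- expand.grid(c0 = c_grid, d0 = d_grid)
  starts <- starts[seq_len(min(nrow(starts), max(n_starts, 5L))), , drop = FALSE]

  b0 <- values[1]                      # value nearest t = 0
  a0 <- values[length(values)]         # late plateau
  span <- diff(range(values))
  lower <- c(a = min(values) - 2 * span, b = min(values) - 2 * span, c = 1e-6, d = 0.05)
  upper <- c(a = max(values) + 2 * span, b = max(values) + 2 * span, c = max(times) * 100, d = 50)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(a = a0, b = b0, c = starts$c0[i], d = starts$d0[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ a + (b - a) / (1 + (t / c)^d),
        data = list(t = times, v = values),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- new_model(stats::coef(fit), rss, converged = TRUE)
  }
  if (is.null(best)) {
    if (on_fail == "error") .stopf("sigmoid fit failed to converge from any start")
    .warnf("sigmoid fit did not converge; returning flat fallback")
    v <- mean(values)
    return(new_model(c(a = v, b = v, c = stats::median(tp), d = 1),
                     rss = sum((values - v)^2), converged = FALSE))
  }
  best
}

#' @export
predict.sigmoid_model <- function(object, newdata, ...) {
  t <- if (is.list(newdata)) newdata[[1]] else newdata
  p <- object$par
  logistic4(t, p[["a"]], p[["b"]], p[["c"]], p[["d"]])
}

#' @export
print.sigmoid_model <- function(x, ...) {
  cat("4-parameter sigmoid fit\n")
  cat(sprintf("  a = %.6g, b = %.6g, c = %.6g, d = %.6g\n",
              x$par[["a"]], x$par[["b"]], x$par[["c"]], x$par[["d"]]))
  cat(sprintf("  rss = %.4g over %d points (%s)\n", x$rss, x$n,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
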