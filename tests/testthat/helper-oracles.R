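# Independent oracles used to check the package's numerics. These stay
# deliberately naive (enumeration, direct integration) and never call the
# code paths they verify.

# Brute-force solution of min ||sqrt(w) (y - A x)||^2, x >= 0 by exhaustive
# active-set enumeration: try every support set, solve the unconstrained
# weighted LS on it, and accept the candidate that is feasible and satisfies
# the KKT conditions on the zero coordinates.
qp_nnls_oracle <- function(A, y, w = rep(1, length(y)), tol = 1e-9) {
  A <- as.matrix(A)
  p <- ncol(A)
  sw <- sqrt(w)
  Aw <- sw * A
  yw <- sw * y
  best <- NULL
  for (mask in 0:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    x <- rep(0, p)
    if (length(S)) {
      xs <- tryCatch(qr.solve(Aw[, S, drop = FALSE], yw), error = function(e) NULL)
      if (is.null(xs) || any(!is.finite(xs))) next
      if (any(xs < -tol)) next
      x[S] <- pmax(xs, 0)
    }
    r <- yw - Aw %*% x
    grad <- -2 * crossprod(Aw, r)      # df/dx
    if (any(grad[setdiff(seq_len(p), S)] < -1e-7)) next
    rss <- sum(r^2)
    if (is.null(best) || rss < best$rss - tol) best <- list(x = x, rss = rss)
  }
  best
}

# Direct numeric convolution of a sampled input curve with exp(-beta t),
# evaluated at chosen times by trapezoid integration on a fine grid.
dense_conv_oracle <- function(time, value, beta, t_eval, dt = 0.05) {
  vapply(t_eval, function(te) {
    if (te <= 0) return(0)
    s <- seq(0, te, by = dt)
    u <- approx(time, value, xout = s, rule = 2)$y
    u[s < time[1]] <- 0
    integrand <- u * exp(-beta * (te - s))
    sum((integrand[-1] + integrand[-length(integrand)]) / 2 * diff(s))
  }, numeric(1))
}

# Exact two-condition Friedman p by enumerating every within-subject swap.
sign_perm_friedman_oracle <- function(m) {
  n <- nrow(m)
  obs <- unname(stats::friedman.test(m)$statistic)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    mm <- m
    flip <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    mm[flip, ] <- mm[flip, 2:1]
    if (unname(stats::friedman.test(mm)$statistic) >= obs - 1e-12)
      count <- count + 1L
  }
  count / 2^n
}
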