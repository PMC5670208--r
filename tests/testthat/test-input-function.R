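test_that("identity ratio and parent sigmoids leave the curves unchanged", {
  b <- gen_blood_dataset(list(ratio = c(a = 1, b = 1, c = 5, d = 1),
                              parent = c(a = 1, b = 1, c = 5, d = 1)))
  expect_true(all(b$discrete$parent_fraction[!is.na(b$discrete$parent_fraction)] == 1))
  expect_equal(b$discrete$plasma, b$discrete$whole_blood)
  pc <- suppressMessages(build_plasma_curve(b, fit_plasma_ratio(b)))
  early <- pc$time_s <= 900
  expect_equal(pc$plasma[early], b$continuous$whole_blood, tolerance = 1e-6)
  ifn <- apply_parent_correction(pc, fit_parent_fraction(b))
  expect_equal(ifn$parent_plasma_activity, pc$plasma)
})

test_that("a constant-half parent model halves the plasma curve exactly", {
  b <- fixture_blood()
  pc <- suppressMessages(build_plasma_curve(b, fit_plasma_ratio(b)))
  half <- fit_sigmoid(c(1, 5, 10, 30, 60), rep(0.5, 5))
  ifn <- apply_parent_correction(pc, half)
  expect_equal(ifn$parent_plasma_activity, pc$plasma / 2)
})

test_that("generator round trip recovers the plasma and parent curves", {
  b <- fixture_blood()
  p <- b$params
  pc <- suppressMessages(build_plasma_curve(b, fit_plasma_ratio(b)))
  ifn <- apply_parent_correction(pc, fit_parent_fraction(b))
  # truth on the merged grid
  tmin <- ifn$time_s / 60
  wb <- cb1quant:::.wb_curve(ifn$time_s, p)
  truth <- wb *
    logistic4(tmin, p$ratio[["a"]], p$ratio[["b"]], p$ratio[["c"]], p$ratio[["d"]]) *
    logistic4(tmin, p$parent[["a"]], p$parent[["b"]], p$parent[["c"]], p$parent[["d"]])
  rel_rms <- sqrt(mean((ifn$parent_plasma_activity - truth)^2)) /
    sqrt(mean(truth^2))
  expect_lt(rel_rms, 0.005)
})

test_that("the input function scales linearly with the blood activities", {
  b1 <- fixture_blood()
  b2 <- gen_blood_dataset(list(wb_peak = b1$params$wb_peak * 3), seed = 42)
  mk <- function(b) suppressMessages(
    apply_parent_correction(build_plasma_curve(b, fit_plasma_ratio(b)),
                            fit_parent_fraction(b)))
  i1 <- mk(b1); i2 <- mk(b2)
  expect_equal(i2$parent_plasma_activity, 3 * i1$parent_plasma_activity,
               tolerance = 1e-6)
})

test_that("the merged curve stays close to truth across the 15-minute junction", {
  b <- fixture_blood()
  p <- b$params
  pc <- suppressMessages(build_plasma_curve(b, fit_plasma_ratio(b)))
  # just after the continuous record ends, the merged curve interpolates
  # between the 15-min grid end and the 20-min discrete sample; it must
  # track the generating plasma curve closely there
  for (ts in c(899, 1000, 1100, 1199)) {
    got <- approx(pc$time_s, pc$plasma, xout = ts)$y
    truth <- cb1quant:::.wb_curve(ts, p) *
      logistic4(ts / 60, p$ratio[["a"]], p$ratio[["b"]], p$ratio[["c"]], p$ratio[["d"]])
    expect_lt(abs(got - truth) / truth, 0.05)
  }
})

test_that("zero blood gives a zero curve and bad sigmoids are caught", {
  b <- gen_blood_dataset(list(wb_peak = 0))
  ratio <- fit_sigmoid(c(3, 5, 10, 15, 20, 30), rep(1, 6))
  pc <- suppressMessages(build_plasma_curve(b, ratio))
  expect_true(all(pc$plasma == 0))
  neg <- fit_sigmoid(c(1, 5, 10, 30, 60), rep(-0.5, 5))
  expect_error(suppressMessages(build_plasma_curve(fixture_blood(), neg)),
               "negative ratios")
  expect_error(gen_blood_dataset(list(wb_peak = NA)), "non-finite")
})

test_that("arrival delay is recovered from shifted synthetic data", {
  ifn <- fixture_input()
  sch <- fixture_schedule()
  kp <- kinetic_params("one_tissue", K1 = 0.24, k2 = 0.06, delay_s = 5)
  tac <- gen_tissue_tac(ifn, kp, sch)
  est <- estimate_delay(ifn, tac, sch, delays = seq(-10, 10, 0.5))
  expect_lte(abs(est$delay_s - 5), 0.5)
  expect_equal(attr(apply_delay(ifn, est$delay_s), "delay_applied"), est$delay_s)

  kp0 <- kinetic_params("one_tissue", K1 = 0.24, k2 = 0.06)
  tac0 <- gen_tissue_tac(ifn, kp0, sch)
  est0 <- estimate_delay(ifn, tac0, sch, delays = seq(-10, 10, 0.5))
  expect_lte(abs(est0$delay_s), 0.5)
})

test_that("a pure-noise TAC triggers a degenerate-delay warning", {
  ifn <- fixture_input()
  sch <- fixture_schedule()
  set.seed(7)
  noise <- rnorm(35)
  expect_warning(
    estimate_delay(ifn, noise, sch, delays = seq(-6, 6, 2), n_beta = 15),
    "boundary|flat")
})
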