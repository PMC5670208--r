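test_that("basis columns match a direct dense convolution oracle", {
  ifn <- fixture_input()
  sch <- frame_schedule(c(30, 60, 120, 300))
  basis <- build_basis(ifn, sch, n_beta = 5)
  # oracle: direct integral evaluated on a 16-interval grid per frame,
  # frame-averaged by the trapezoid rule -- fully independent of the
  # package's recursive convolution
  for (j in c(1, 3, 5)) {
    beta <- basis$beta[j]
    for (i in seq_len(nrow(sch))) {
      tt <- seq(sch$frame_start_s[i],
                sch$frame_start_s[i] + sch$frame_dur_s[i], length.out = 17)
      vv <- dense_conv_oracle(ifn$time_s, ifn$parent_plasma_activity, beta, tt)
      avg <- sum((vv[-1] + vv[-17]) / 2 * diff(tt)) / sch$frame_dur_s[i]
      expect_equal(basis$basis[i, j], avg, tolerance = 0.01)
    }
  }
})

test_that("the slow-frequency limit approaches the running integral", {
  ifn <- fixture_input()
  sch <- frame_schedule(c(60, 300, 600))
  basis <- build_basis(ifn, sch, beta_slow = 1e-7, beta_fast = 1e-6, n_beta = 2)
  u <- cb1quant:::.dense_curve(ifn$time_s, ifn$parent_plasma_activity, 960, 1)
  integral <- cumsum(c(0, (u$v[-1] + u$v[-length(u$v)]) / 2))
  run_int <- cb1quant:::.frame_average(integral, 1, sch)
  expect_equal(basis$basis[, 1], run_int, tolerance = 1e-3)
})

test_that("basis dimensions and validation behave", {
  ifn <- fixture_input()
  sch <- fixture_schedule()
  b2 <- build_basis(ifn, sch, n_beta = 2)
  expect_equal(dim(b2$basis), c(35L, 2L))
  expect_length(b2$blood, 35)                  # vascular column alongside
  expect_error(build_basis(ifn, sch, beta_slow = 0.2, beta_fast = 0.1),
               "beta_slow < beta_fast")
  expect_error(build_basis(ifn, sch, n_beta = 1), ">= 2")
})

test_that("noise-free one- and two-tissue VT are recovered within 1%", {
  ifn <- fixture_input()
  sch <- fixture_schedule()
  basis <- fixture_basis()
  for (kp in list(kinetic_params("one_tissue", K1 = 0.24, k2 = 0.06),
                  kinetic_params("two_tissue", K1 = 0.4, k2 = 0.2,
                                 k3 = 0.05, k4 = 0.1))) {
    tac <- gen_tissue_tac(ifn, kp, sch)
    fit <- fit_spectral(tac, basis, weights = frame_weights(tac))
    expect_lt(abs(fit$vt - analytic_vt(kp)) / analytic_vt(kp), 0.01)
  }
})

test_that("a pure-blood TAC is explained by the vascular term alone", {
  sch <- fixture_schedule()
  basis <- fixture_basis()
  fit <- fit_spectral(basis$blood, basis, weights = rep(1, 35))
  expect_gt(fit$vb, 0.98)
  expect_lt(fit$vt, 0.05)
})

test_that("VT scales with the TAC and is invariant to joint scaling", {
  ifn <- fixture_input()
  sch <- fixture_schedule()
  basis <- fixture_basis()
  kp <- kinetic_params("one_tissue", K1 = 0.24, k2 = 0.06)
  tac <- gen_tissue_tac(ifn, kp, sch)
  w <- frame_weights(tac)
  f1 <- fit_spectral(tac$activity, basis, weights = w, vb = 0)
  f2 <- fit_spectral(2 * tac$activity, basis, weights = w, vb = 0)
  expect_equal(f2$vt, 2 * f1$vt, tolerance = 1e-6)
  # doubling input and TAC together: rebuild basis from the scaled input
  ifn2 <- ifn
  ifn2$parent_plasma_activity <- 2 * ifn2$parent_plasma_activity
  basis2 <- suppressMessages(
    build_basis(structure(ifn2, delay_applied = 0, blood = NULL,
                          class = class(ifn)), sch))
  f3 <- fit_spectral(2 * tac$activity, basis2, weights = w, vb = 0)
  expect_equal(f3$vt, f1$vt, tolerance = 1e-6)
})

test_that("the NNLS solution matches the brute-force active-set QP oracle", {
  set.seed(11)
  for (rep in 1:20) {
    nfr <- 12; p <- 8
    A <- matrix(abs(rnorm(nfr * p)), nfr)
    xtrue <- pmax(rnorm(p, 0, 1), 0)
    y <- A %*% xtrue + rnorm(nfr, 0, 0.3)
    w <- runif(nfr, 0.5, 2)
    ours <- spectral_nnls(A, y, w)
    oracle <- qp_nnls_oracle(A, y, w)
    expect_lt(max(abs(ours$x - oracle$x)), 1e-6)
    expect_equal(ours$rss, oracle$rss, tolerance = 1e-8)
  }
})

test_that("the fallback active-set solver agrees with the oracle too", {
  set.seed(77)
  for (rep in 1:10) {
    A <- matrix(abs(rnorm(12 * 7)), 12)
    y <- as.numeric(A %*% pmax(rnorm(7), 0) + rnorm(12, 0, 0.3))
    x_fb <- cb1quant:::.nnls_lawson_hanson(A, y)
    oracle <- qp_nnls_oracle(A, y)
    expect_lt(max(abs(x_fb - oracle$x)), 1e-6)
  }
})

test_that("the full spectral fit agrees with the oracle through the basis path", {
  ifn <- fixture_input()
  sch <- frame_schedule(c(30, 60, 60, 120, 300, 600, 600, 1200))
  basis <- build_basis(ifn, sch, n_beta = 8)
  set.seed(3)
  y <- as.numeric(basis$basis %*% pmax(rnorm(8, 0, 1e-3), 0)) + rnorm(8, 0, 0.1)
  w <- runif(8, 0.5, 2)
  fit <- fit_spectral(y, basis, weights = w, vb = 0)
  oracle <- qp_nnls_oracle(basis$basis, y, w)
  expect_equal(sum(oracle$x / basis$beta), fit$vt, tolerance = 1e-6)
})

test_that("rank shaping preserves coefficient mass and plain mode is default", {
  ifn <- fixture_input()
  sch <- fixture_schedule()
  basis <- fixture_basis()
  kp <- kinetic_params("one_tissue", K1 = 0.24, k2 = 0.06)
  tac <- gen_tissue_tac(ifn, kp, sch, noise_scale = 1, seed = 5)
  w <- frame_weights(tac)
  plain <- fit_spectral(tac, basis, weights = w)
  shaped <- fit_spectral(tac, basis, weights = w, regularisation = "rank_shaping")
  expect_equal(sum(shaped$alpha), sum(plain$alpha), tolerance = 1e-8)
  expect_identical(plain$regularisation, "none")
  # shaping must not destroy VT recovery
  expect_lt(abs(shaped$vt - 4) / 4, 0.1)
})

test_that("degenerate spectral inputs are signalled", {
  basis <- fixture_basis()
  expect_error(fit_spectral(rep(1, 35), basis, weights = rep(0, 35)),
               "all frame weights are zero")
  expect_error(fit_spectral(rep(1, 10), basis, weights = rep(1, 10)), "frames")
  expect_error(fit_spectral(rep(1, 35), basis, weights = rep(1, 35), vb = 2),
               "vb")
})

test_that("the slow boundary sits above the physical decay constant", {
  basis <- fixture_basis()
  expect_gt(min(basis$beta), decay_constant(20.4))
})

test_that("ROI extraction averages exactly over labelled voxels", {
  sch <- frame_schedule(c(60, 60, 60))
  img <- array(0, c(2, 2, 1, 3))
  img[1, 1, 1, ] <- c(1, 2, 3)
  img[2, 1, 1, ] <- c(3, 4, 5)
  img[1, 2, 1, ] <- 7
  lab <- array(c(1L, 1L, 2L, 0L), c(2, 2, 1))
  expect_equal(roi_mean_tac(img, lab, 1), c(2, 3, 4))       # two-voxel mean
  expect_equal(roi_mean_tac(img, lab, 2), c(7, 7, 7))       # single voxel
  uni <- array(5, c(2, 2, 1, 3))
  expect_equal(roi_mean_tac(uni, lab, 1), c(5, 5, 5))
  tt <- roi_mean_tac(img, lab, 1, schedule = sch, region = "amygdala")
  expect_s3_class(tt, "tissue_tac")
  expect_equal(attr(tt, "region"), "amygdala")
  expect_error(roi_mean_tac(img, lab, 9), "absent")
  expect_error(roi_mean_tac(img, array(1L, c(3, 2, 1)), 1), "grid")
})
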