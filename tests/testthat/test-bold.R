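test_that("regressors superpose shifted unit-peak kernels", {
  empty <- gamma_hrf_regressors(numeric(0), character(0), tr = 2, n_volumes = 60)
  expect_true(all(empty == 0))
  one <- gamma_hrf_regressors(10, "fearful", tr = 2, n_volumes = 60,
                              contrast = c(fearful = 1))
  expect_equal(max(one[, 1]), 1, tolerance = 1e-3)      # unit-peak kernel
  expect_lt(max(abs(one[(1:5), ])), 1e-10)              # nothing before onset
  two <- gamma_hrf_regressors(c(10, 70), c("fearful", "fearful"), tr = 2,
                              n_volumes = 60, contrast = c(fearful = 1))
  shifted <- gamma_hrf_regressors(70, "fearful", tr = 2, n_volumes = 60,
                                  contrast = c(fearful = 1))
  expect_equal(two, one + shifted, tolerance = 1e-9)    # superposition
  expect_error(gamma_hrf_regressors(10, "x", tr = 2, n_volumes = 60), "contrast")
  expect_error(gamma_hrf_regressors(10, "fearful", tr = 2, n_volumes = 10),
               "exceeds the run length")
})

test_that("SSQ ratio caps on perfect fits and vanishes off-model", {
  X <- gamma_hrf_regressors(make_stimulus_table(30, isi_s = 8)$onset_s,
                            make_stimulus_table(30, isi_s = 8)$valence,
                            tr = 2, n_volumes = 140)
  f <- fit_ssq(X[, 1], X)                 # time series equal to a regressor
  expect_true(f$capped)
  expect_gte(f$ssq_ratio, 1e6)
  set.seed(4)
  y <- rnorm(140)
  y_orth <- y - X %*% qr.solve(X, y)      # orthogonal to both regressors
  f0 <- fit_ssq(y_orth, X)
  expect_lt(f0$ssq_ratio, 1e-10)
  fc <- fit_ssq(rep(3, 140), X)
  expect_equal(fc$ssq_ratio, 0)           # constant series: ratio defined 0
})

test_that("SSQ ratio is invariant to offset and scaling of the series", {
  stim <- make_stimulus_table(30, isi_s = 8)
  X <- gamma_hrf_regressors(stim$onset_s, stim$valence, tr = 2, n_volumes = 140)
  set.seed(9)
  y <- 0.5 * X[, 1] + rnorm(140)
  r0 <- fit_ssq(y, X)$ssq_ratio
  expect_equal(fit_ssq(y + 100, X)$ssq_ratio, r0, tolerance = 1e-9)
  expect_equal(fit_ssq(y * 3.7, X)$ssq_ratio, r0, tolerance = 1e-9)
})

test_that("median SSQ ratio grows with the true effect amplitude", {
  stim <- make_stimulus_table(30, isi_s = 8)
  X <- gamma_hrf_regressors(stim$onset_s, stim$valence, tr = 2, n_volumes = 140)
  set.seed(15)
  med <- vapply(c(0, 0.5, 1, 2), function(a) {
    stats::median(vapply(1:100, function(i) {
      fit_ssq(a * X[, 1] + rnorm(140), X)$ssq_ratio
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("permutation p is minimal for self-fit, reproducible, and valid", {
  stim <- make_stimulus_table(30, isi_s = 8)
  X <- gamma_hrf_regressors(stim$onset_s, stim$valence, tr = 2, n_volumes = 140)
  p_self <- permutation_p(X[, 1] + 1e-9, X, n_perm = 199, seed = 1)
  expect_equal(p_self$p_value, 1 / 200)
  set.seed(2)
  y <- rnorm(140)
  expect_identical(permutation_p(y, X, n_perm = 199, seed = 7)$p_value,
                   permutation_p(y, X, n_perm = 199, seed = 7)$p_value)
  pb <- permutation_p(y, X, n_perm = 199, scheme = "block_permute", seed = 3)
  expect_true(pb$p_value > 0 && pb$p_value <= 1)
  expect_error(permutation_p(rep(1, 140), X, n_perm = 199), "degenerate")
  expect_error(permutation_p(y, X, n_perm = 10), ">= 100")
})

test_that("null permutation p-values are close to uniform", {
  stim <- make_stimulus_table(30, isi_s = 8)
  X <- gamma_hrf_regressors(stim$onset_s, stim$valence, tr = 2, n_volumes = 140)
  ps <- vapply(1:200, function(i) {
    set.seed(20000 + i)
    permutation_p(rnorm(140), X, n_perm = 199, seed = i)$p_value
  }, numeric(1))
  D <- suppressWarnings(stats::ks.test(ps, "punif")$statistic)
  expect_lt(unname(D), 0.1)
})

test_that("group median test: A = B gives no clusters; effects are recovered", {
  dims <- c(12, 12, 12)
  set.seed(33)
  base <- array(rnorm(prod(dims) * 8), c(dims, 8))
  ct0 <- group_median_test(base, base, n_perm = 100, seed = 1)
  expect_equal(nrow(ct0), 0)

  mask <- cuboid_mask(dims, c(4, 4, 4), c(8, 8, 8))
  m <- gen_group_maps(dims, n_subjects = 14, effect_mask = mask,
                      effect_size = 1.5, seed = 5)
  ct <- group_median_test(m$A, m$B, n_perm = 100, seed = 5)
  expect_gte(sum(ct$significant), 1)
  lab <- attr(ct, "cluster_labels")
  det <- array(lab %in% ct$cluster[ct$significant] & lab > 0, dims)
  jac <- sum(det & mask) / sum(det | mask)
  expect_gte(jac, 0.5)
  expect_error(group_median_test(m$A[, , , 1, drop = FALSE],
                                 m$B[, , , 1, drop = FALSE]),
               "two subjects")
})

test_that("median group statistic resists single-subject corruption", {
  dims <- c(10, 10, 10)
  m <- gen_group_maps(dims, n_subjects = 9, seed = 6)
  D <- matrix(m$A - m$B, prod(dims), 9)
  med1 <- cb1quant:::.row_medians(D)
  D2 <- D
  D2[, 5] <- D2[, 5] + 1e6
  med2 <- cb1quant:::.row_medians(D2)
  spread <- apply(D, 1, function(r) diff(range(r)))
  expect_true(all(abs(med2 - med1) <= spread + 1e-9))
})

test_that("connected components use face connectivity", {
  m <- array(FALSE, c(4, 4, 1))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE     # diagonal: two components
  lab <- cb1quant:::.label_components(m)
  expect_equal(max(lab), 2)
  m[2, 1, 1] <- TRUE                          # bridge: one component
  expect_equal(max(cb1quant:::.label_components(m)), 1)
})
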