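test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_blood_dataset(list(noise_cv = 0.05), seed = 1),
                   gen_blood_dataset(list(noise_cv = 0.05), seed = 1))
  stim <- make_stimulus_table(20)
  expect_identical(gen_scr_session(stim, seed = 4), gen_scr_session(stim, seed = 4))
  sp <- cohort_spec(seed = 9)
  expect_identical(gen_cohort(sp), gen_cohort(sp))
  expect_identical(gen_symptom_table(sp), gen_symptom_table(sp))
  ifn <- fixture_input()
  sch <- fixture_schedule()
  kp <- kinetic_params("one_tissue", K1 = 0.24, k2 = 0.06)
  expect_identical(gen_tissue_tac(ifn, kp, sch, noise_scale = 1, seed = 2),
                   gen_tissue_tac(ifn, kp, sch, noise_scale = 1, seed = 2))
})

test_that("noise-free one-tissue TAC carries VT = K1/k2 recoverable at 1%", {
  ifn <- fixture_input()
  sch <- fixture_schedule()
  kp <- kinetic_params("one_tissue", K1 = 0.24, k2 = 0.06)   # VT = 4
  tac <- gen_tissue_tac(ifn, kp, sch)
  fit <- fit_spectral(tac, fixture_basis(), weights = frame_weights(tac))
  expect_lt(abs(fit$vt - 4) / 4, 0.01)
  # and the analytic convolution agrees with a direct numeric oracle
  theta <- kp$k2 / 60
  t3 <- c(300, 1500, 4000)
  oracle <- (kp$K1 / 60) *
    dense_conv_oracle(ifn$time_s, ifn$parent_plasma_activity, theta, t3, dt = 0.25)
  u <- cb1quant:::.dense_curve(ifn$time_s, ifn$parent_plasma_activity, 5700, 0.5)
  ours <- (kp$K1 / 60) * cb1quant:::.exp_conv(u$v, 0.5, theta)[t3 / 0.5 + 1]
  expect_equal(ours, oracle, tolerance = 0.002)
})

test_that("vb = 1 with vanishing kinetics returns the frame-averaged blood", {
  ifn <- fixture_input()
  sch <- fixture_schedule()
  kp <- kinetic_params("one_tissue", K1 = 1e-9, k2 = 1e-3, vb = 1)
  tac <- gen_tissue_tac(ifn, kp, sch)
  b <- attr(ifn, "blood")
  wb_t <- c(b$continuous$time_s, b$discrete$time_min * 60)
  wb_v <- c(b$continuous$whole_blood, b$discrete$whole_blood)
  o <- order(wb_t)
  wb <- cb1quant:::.dense_curve(wb_t[o], wb_v[o], 5700, 0.5)
  wb_f <- cb1quant:::.frame_average(wb$v, 0.5, sch)
  expect_equal(tac$activity, wb_f, tolerance = 1e-6)
})

test_that("empty schedules and invalid kinetics are rejected", {
  expect_error(kinetic_params("one_tissue", K1 = -1, k2 = 0.1), "> 0")
  expect_error(kinetic_params("two_tissue", K1 = 1, k2 = 0.1), "k3")
  expect_error(kinetic_params("one_tissue", K1 = 1, k2 = 0.1, vb = 1.4), "vb")
  expect_equal(analytic_vt(kinetic_params("two_tissue", K1 = 0.4, k2 = 0.2,
                                          k3 = 0.05, k4 = 0.1)), 3)
})

test_that("SCR generator honours probability, floor and valence offset", {
  stim <- make_stimulus_table(60)
  s0 <- gen_scr_session(stim, list(response_prob = 0), seed = 1)
  expect_equal(nrow(s0$events), 0)
  s1 <- gen_scr_session(stim, list(response_prob = 1, amp_floor = 0.05,
                                   fear_amp_offset = 0.08), seed = 1)
  expect_equal(nrow(s1$events), 60)
  expect_true(all(s1$events$latency_s >= 0.5 & s1$events$latency_s <= 3))
  expect_true(all(s1$events$amplitude_uS >= 0.05))
  amp_by_val <- tapply(s1$events$amplitude_uS, s1$events$valence, mean)
  expect_gt(amp_by_val[["fearful"]], amp_by_val[["neutral"]])
  close_stim <- data.frame(onset_s = c(5, 6), valence = c("neutral", "fearful"))
  expect_error(gen_scr_session(close_stim), "minimum ISI")
})

test_that("placebo ratings have zero change variance and drug effect scales", {
  sp <- cohort_spec(seed = 21)
  rt <- gen_symptom_table(sp)
  pl <- rt[rt$condition == "placebo", ]
  v <- tapply(pl$value, interaction(pl$subject, pl$scale), stats::var)
  expect_true(all(v == 0))
  expect_true(all(rt$value[rt$scale == "STAI-S"] >= 20 &
                    rt$value[rt$scale == "STAI-S"] <= 80))
  # effect 0: drug identical to placebo, so the AUC distributions match
  rt0 <- gen_symptom_table(sp, effect_scale = 0)
  auc_by <- function(d, cond) {
    d <- d[d$scale == "STAI-S" & d$condition == cond, ]
    vapply(split(d, d$subject),
           function(x) auc_trapezoid(x$time_h[order(x$time_h)],
                                     x$value[order(x$time_h)]), numeric(1))
  }
  expect_equal(auc_by(rt0, "drug"), auc_by(rt0, "placebo"))
})

test_that("cohort VT respects the truncation range and spec validation", {
  sp <- cohort_spec(n_subjects = 200, seed = 5)
  co <- gen_cohort(sp)
  expect_true(all(co$vt_right_amygdala >= 7.51 & co$vt_right_amygdala <= 17.75))
  expect_equal(nrow(co), 200)
  sp3 <- cohort_spec(n_subjects = 3, seed = 1)
  expect_equal(nrow(gen_cohort(sp3)), 3)
  expect_false(identical(gen_cohort(cohort_spec(n_subjects = 3, seed = 1)),
                         gen_cohort(cohort_spec(n_subjects = 3, seed = 2))))
  expect_error(cohort_spec(n_subjects = 2), ">= 3")
  expect_error(cohort_spec(anxiety_effect_corr = 1.2), "correlations")
  expect_error(cohort_spec(vt_sd = 0), "vt_sd")
})

test_that("zero requested correlations produce independent outcomes", {
  sp <- cohort_spec(n_subjects = 10000, anxiety_effect_corr = 0,
                    ssq_effect_corr = 0, seed = 8)
  co <- gen_cohort(sp)
  expect_lt(abs(cor(co$vt_right_amygdala, co$anxiety_delta)), 0.1)
  expect_lt(abs(cor(co$vt_right_amygdala, co$ssq_effect)), 0.1)
})

test_that("requested VT-anxiety correlation survives the ratings pathway", {
  rs <- vapply(1:60, function(i) {
    sp <- cohort_spec(n_subjects = 200, anxiety_effect_corr = 0.9, seed = 4000 + i)
    rt <- gen_symptom_table(sp)
    co <- attr(rt, "cohort")
    d <- rt[rt$scale == "STAI-S", ]
    wm <- function(s, cond) {
      x <- d[d$subject == s & d$condition == cond, ]
      window_mean_1_2h(x$time_h, x$value)
    }
    delta <- vapply(co$subject, function(s) wm(s, "drug") - wm(s, "placebo"),
                    numeric(1))
    cor(co$vt_right_amygdala, delta)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.9), 0.03)
})
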