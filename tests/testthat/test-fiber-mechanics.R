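# Protocol segmentation, viscoelastic decomposition, timecourse
# normalization, correlations and active force drops.

test_that("protocol segmentation finds the six stretch-hold steps", {
  m <- viscoelastic_model(1, data.frame(k = 0.5, tau = 2), noise_sd = 0)
  tr <- gen_ramp_hold_trace(m, default_ramp_protocol(), seed = 1)
  ph <- segment_protocol(tr)
  holds <- ph[ph$phase == "hold" & ph$start > 1, ]
  ramps <- ph[ph$phase == "ramp", ]
  expect_equal(nrow(ramps), 6)
  expect_equal(nrow(holds), 6)
  expect_equal(holds$target_sl, c(2.4, 2.6, 2.8, 3.0, 3.2, 3.4),
               tolerance = 1e-6)

  expect_error(segment_protocol(
    structure(data.frame(time_s = 0:10, sl_um = 2.2, force = 0),
              class = c("force_trace", "data.frame"))), "constant")

  # robustness: 1% SL noise leaves the hold plateaus unchanged
  trn <- tr
  set.seed(42)
  trn$sl_um <- tr$sl_um + rnorm(nrow(tr), 0, 0.01 * diff(range(tr$sl_um)))
  phn <- segment_protocol(trn, smooth_s = 0.5)
  holds_n <- phn[phn$phase == "hold" & phn$start > 1, ]
  expect_equal(sort(round(holds_n$target_sl, 1)),
               c(2.4, 2.6, 2.8, 3.0, 3.2, 3.4))
})

test_that("elastic/viscous decomposition matches the analytic SLS response", {
  # pure spring: viscous ~ 0, elastic = k * dSL
  m0 <- viscoelastic_model(1.5, baseline_fraction = 0, noise_sd = 0)
  tr0 <- gen_ramp_hold_trace(m0, default_ramp_protocol(), seed = 1)
  de0 <- decompose_viscoelastic(tr0)
  expect_equal(de0$viscous, rep(0, 6), tolerance = 1e-9)
  expect_equal(de0$elastic, 1.5 * (de0$sl_um - 2.2), tolerance = 1e-6)

  # SLS: per-step elastic and viscous within 2% of the closed form
  m1 <- viscoelastic_model(1, data.frame(k = 1, tau = 2),
                           baseline_fraction = 0, noise_sd = 0)
  tr1 <- gen_ramp_hold_trace(m1, default_ramp_protocol(), seed = 1)
  de1 <- decompose_viscoelastic(tr1)
  orc <- oracle_sls_steps(1, 1, 2)
  expect_equal(de1$peak, orc$peak, tolerance = 0.02)
  expect_equal(de1$elastic, orc$elastic, tolerance = 0.02)
  expect_equal(de1$viscous / de1$elastic,
               (orc$peak - orc$elastic) / orc$elastic, tolerance = 0.02)

  # additivity: elastic + viscous = ramp-end peak, per step
  expect_equal(de1$elastic + de1$viscous, de1$peak, tolerance = 1e-12)

  # linear scaling with titin fraction at fixed baseline
  mk <- function(tf) viscoelastic_model(1, data.frame(k = 1, tau = 2),
                                        titin_fraction = tf,
                                        baseline_fraction = 0.4, noise_sd = 0)
  d1 <- decompose_viscoelastic(gen_ramp_hold_trace(mk(1), default_ramp_protocol(), seed = 1))
  d5 <- decompose_viscoelastic(gen_ramp_hold_trace(mk(0.5), default_ramp_protocol(), seed = 1))
  scale <- (0.4 + 0.6 * 0.5) / 1
  expect_equal(d5$elastic, scale * d1$elastic, tolerance = 1e-9)
  expect_equal(d5$viscous, scale * d1$viscous, tolerance = 1e-6)
})

test_that("SLS parameter recovery from generator output is within 5%", {
  m <- viscoelastic_model(1.2, data.frame(k = 0.8, tau = 2),
                          baseline_fraction = 0, noise_sd = 0.01)
  tr <- gen_ramp_hold_trace(m, default_ramp_protocol(), seed = 3)
  de <- decompose_viscoelastic(tr)
  # k_elastic from the elastic-vs-SL slope (subtracting the small arm
  # residual is unnecessary at 5% tolerance)
  k_el_hat <- coef(lm(elastic ~ sl_um, de))[2]
  expect_equal(unname(k_el_hat), 1.2, tolerance = 0.05)
  # arm stiffness from the steady-state viscous component:
  # k_m = viscous / (v * tau * (1 - e^(-T/tau)) ... use the analytic ratio
  orc <- oracle_sls_steps(1.2, 0.8, 2)
  expect_equal(mean(de$viscous[-1]), mean((orc$peak - orc$elastic)[-1]),
               tolerance = 0.05)
})

test_that("timecourse normalization is exact, anchored at 1, and idempotent", {
  # identity: treated == control -> flat 1.0
  tr <- gen_hold_timecourse(cleave_tau_min = Inf, noise_sd = 0, seed = 1)
  tc <- normalize_timecourse(tr, tr)
  expect_equal(tc$normalized_force, rep(1, 11), tolerance = 1e-12)

  # decay arithmetic: titin share 0.6744 with tau = 4 min -> 0.3256 at 30
  treated <- gen_hold_timecourse(titin_share = 0.6744, cleave_tau_min = 4,
                                 noise_sd = 0, seed = 1)
  control <- gen_hold_timecourse(titin_share = 0.6744, cleave_tau_min = Inf,
                                 noise_sd = 0, seed = 2)
  tc2 <- normalize_timecourse(treated, control)
  expect_equal(tc2$normalized_force[1], 1)
  expect_equal(tc2$normalized_force[11],
               0.6744 * exp(-30 / 4) + (1 - 0.6744), tolerance = 0.01)
  expect_equal(percent_force_removed(1, tc2$normalized_force[11]), 67.44,
               tolerance = 0.1)

  # idempotence: re-normalizing the normalized series against a flat
  # control reproduces it
  renorm_in <- structure(data.frame(time_s = tc2$time_min * 60,
                                    sl_um = 3.3,
                                    force = tc2$normalized_force),
                         class = c("force_trace", "data.frame"))
  flat <- structure(data.frame(time_s = tc2$time_min * 60, sl_um = 3.3,
                               force = 1),
                    class = c("force_trace", "data.frame"))
  tc3 <- normalize_timecourse(renorm_in, flat)
  expect_equal(tc3$normalized_force, tc2$normalized_force, tolerance = 1e-9)

  expect_error(normalize_timecourse(treated,
    structure(data.frame(time_s = treated$time_s, sl_um = 3.3, force = 0),
              class = c("force_trace", "data.frame"))), "<= 0")
})

test_that("percent force removed restates the printed arithmetic", {
  expect_equal(percent_force_removed(1.0, 0.3256), 67.44)
  expect_equal(percent_force_removed(1.0, 0.7858), 21.42)
  expect_equal(percent_force_removed(0.8, 0.8), 0)
  expect_error(percent_force_removed(0, 1), "> 0")
})

test_that("force vs intact-titin correlation classifies strength at R^2 = 0.5", {
  # exact line
  f <- 0.2 + 0.8 * c(0, 0.5, 1, 0.25, 0.75)
  # suppress lm's "essentially perfect fit" note on exact data
  fit <- suppressWarnings(
    titin_force_correlation(f, c(0, 0.5, 1, 0.25, 0.75), sl_um = 3.2))
  expect_equal(fit$r_squared, 1)
  expect_identical(fit$strength_class, "strong")

  # long-SL scenario: force ~ 0.5 + 0.5 * fraction + noise
  set.seed(1)
  frac <- rep(c(0, 0.5, 1), each = 6)
  force <- 0.5 + 0.5 * frac + rnorm(length(frac), 0, 0.02)
  fit2 <- titin_force_correlation(force, frac)
  expect_equal(fit2$slope, 0.5, tolerance = 0.1)
  expect_gt(fit2$r_squared, 0.5)
  expect_identical(fit2$strength_class, "strong")

  # short-SL scenario: force independent of fraction
  set.seed(2)
  force0 <- 0.02 + rnorm(length(frac), 0, 0.02)
  fit3 <- titin_force_correlation(force0, frac)
  expect_lt(fit3$r_squared, 0.5)
  expect_identical(fit3$strength_class, "weak")

  expect_error(titin_force_correlation(c(1, 2), c(0, 1)), "3 points")
})

test_that("active force drop uses plateau means and restates printed values", {
  t1 <- gen_activation_trace(plateau = 1, noise_sd = 0, seed = 1)
  t2 <- gen_activation_trace(plateau = 0.5369, noise_sd = 0, seed = 2)
  res <- active_force_drop(t1, t2)
  expect_equal(res$percent_drop, 46.31, tolerance = 0.01)

  same <- active_force_drop(t1, t1)
  expect_equal(same$percent_drop, 0, tolerance = 1e-9)

  # 1% noise: steady-state estimate within 0.5% of the noiseless plateau
  tn <- gen_activation_trace(plateau = 1, noise_sd = 0.01, seed = 3)
  resn <- active_force_drop(t1, tn, plateau_window_s = 10, slope_tol = 0.01)
  expect_equal(resn$steady_state_second, 1, tolerance = 0.005)

  # control correction
  resc <- active_force_drop(t1, t2, control_drop_percent = 5)
  expect_equal(resc$control_corrected_drop, 46.31 - 5, tolerance = 0.01)

  # rising (non-plateaued) trace errors
  rising <- structure(data.frame(time_s = seq(0, 120, 0.01), sl_um = 2.6,
                                 force = seq(0, 120, 0.01) / 120),
                      class = c("force_trace", "data.frame"))
  expect_error(active_force_drop(t1, rising), "plateau")
})
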