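# Synthetic-data generators: geometry, oracles, reproducibility.

test_that("generators are reproducible: identical seeds give identical output", {
  a <- fixture_em(waviness = 15, jitter = 2, seed = 11)
  b <- fixture_em(waviness = 15, jitter = 2, seed = 11)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$zdisk_paths, b$truth$zdisk_paths)

  m <- viscoelastic_model(1, data.frame(k = 1, tau = 2), noise_sd = 0.01)
  t1 <- gen_ramp_hold_trace(m, default_ramp_protocol(n_steps = 2), seed = 5)
  t2 <- gen_ramp_hold_trace(m, default_ramp_protocol(n_steps = 2), seed = 5)
  expect_identical(t1$force, t2$force)

  s <- hertz_curve_spec(4.81, noise_sd_nn = 0.05)
  expect_identical(gen_indentation_curve(s, seed = 3)$force_nn,
                   gen_indentation_curve(s, seed = 3)$force_nn)

  ls <- lane_spec(composition = c(N2A_intact = 0.6, AM_fragment = 0.4),
                  noise_sd = 0.01)
  expect_identical(gen_gel_lane(ls, seed = 9)$intensity,
                   gen_gel_lane(ls, seed = 9)$intensity)
})

test_that("EM micrograph geometry is forced by construction", {
  sim <- gen_em_micrograph(sl_um = 3.3, n_sarcomeres = 5, nm_per_px = 4,
                           height_px = 80, seed = 1)
  expect_gte(ncol(sim$image$pixels), 5 * 3300 / 4)
  expect_length(sim$truth$zdisk_paths, 6)

  # zero perturbation: every path is exactly collinear with its line
  sim0 <- fixture_em(waviness = 0, jitter = 0)
  for (p in sim0$truth$zdisk_paths) {
    seg <- fit_segment_line(zdisk_segment(p))
    expect_lt(max(abs(seg$residuals_nm)), 1e-9)
  }
})

test_that("sinusoidal waviness has RMS amplitude A/sqrt(2) about the fitted line", {
  # integer number of periods across the image height; enough periods
  # that the fitted line cannot absorb the sinusoid (the absorbed
  # variance fraction is 6/(pi^2 k^2) for k periods)
  sim <- gen_em_micrograph(sl_um = 3.0, n_sarcomeres = 2, nm_per_px = 8,
                           height_px = 150, waviness_amplitude_nm = 20,
                           waviness_period_nm = 150 * 8 / 8, seed = 7)
  for (p in sim$truth$zdisk_paths) {
    seg <- fit_segment_line(zdisk_segment(p))
    rms <- sqrt(mean(seg$residuals_nm^2))
    expect_equal(rms, 20 / sqrt(2), tolerance = 0.05)
  }
})

test_that("rendered Z-disk ridges agree with stored paths to within 1 px", {
  sim <- fixture_em(waviness = 25, seed = 13, noise = 0)
  px <- sim$image$pixels
  nmpp <- sim$image$nm_per_px
  for (p in sim$truth$zdisk_paths) {
    for (i in seq(1, nrow(p), by = 25)) {
      row <- round(p[i, 2] / nmpp + 0.5)
      col_true <- p[i, 1] / nmpp + 0.5
      j0 <- max(1, round(col_true - 6)); j1 <- min(ncol(px), round(col_true + 6))
      col_min <- (j0:j1)[which.min(px[row, j0:j1])]
      expect_lte(abs(col_min - col_true), 1)
    }
  }
})

test_that("EM generator rejects invalid parameters", {
  expect_error(gen_em_micrograph(nm_per_px = 0), "nm_per_px")
  expect_error(gen_em_micrograph(sl_um = 3.0, aband_length_nm = 1600,
                                 waviness_amplitude_nm = 800),
               "waviness")
  expect_error(gen_em_micrograph(sl_um = 1.0), "sl_um")
})

test_that("particle placement honours offsets, recoil mixture and counts", {
  em <- fixture_em(seed = 1, noise = 0)
  gt <- em$truth

  # noise-free, no background, no recoil: distances equal the offset
  pf <- gen_particle_field(gt, "N2A", 5, background_rate = 0,
                           recoil_fraction = 0, placement_sd_nm = 0, seed = 2)
  d <- vapply(pf$truth$x_nm, function(x) min(abs(x - gt$zdisk_x_nm)),
              numeric(1))
  expect_equal(d, rep(gt$epitope_offsets_nm[["N2A"]], length(d)),
               tolerance = 1e-12)

  # recoil mixture: two modes at ~50 and ~700 nm
  gt2 <- gt; gt2$epitope_offsets_nm["HaloTag"] <- 700
  pf2 <- gen_particle_field(gt2, "HaloTag", 40, recoil_fraction = 0.5,
                            recoil_offset_nm = 50, placement_sd_nm = 10,
                            seed = 3)
  d2 <- vapply(pf2$truth$x_nm, function(x) min(abs(x - gt$zdisk_x_nm)),
               numeric(1))
  h <- hist(d2, breaks = seq(0, 800, by = 50), plot = FALSE)
  modes <- h$mids[h$counts >= 0.5 * max(h$counts)]
  expect_true(any(abs(modes - 50) <= 50))
  expect_true(any(abs(modes - 700) <= 50))

  # Poisson count calibration: mean per sarcomere within 2 SEM of 93.6
  counts <- numeric(0)
  for (s in 1:5) {
    pfc <- gen_particle_field(gt, "HaloTag", 93.6 / 2, seed = s,
                              placement_sd_nm = 20)
    counts <- c(counts, as.vector(table(factor(pfc$truth$sarcomere,
                                               levels = 1:3))))
  }
  sem <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 93.6), 2 * sem + 1e-9)

  expect_error(gen_particle_field(gt, "N2A", -1), "rates")
  expect_error(gen_particle_field(gt, "N2A", 5, recoil_fraction = 1.5),
               "recoil_fraction")
  expect_error(gen_particle_field(gt, "nope", 5), "epitope")
})

test_that("ramp-hold trace matches the analytic generalized-Maxwell response", {
  # pure spring: force during each hold is constant, k * (SL - slack)
  m0 <- viscoelastic_model(2, baseline_fraction = 0, noise_sd = 0)
  tr0 <- gen_ramp_hold_trace(m0, default_ramp_protocol(n_steps = 3), seed = 1)
  ph <- segment_protocol(tr0)
  for (k in which(ph$phase == "hold" & ph$start > 1)) {
    f_hold <- tr0$force[ph$start[k]:ph$end[k]]
    expect_lt(diff(range(f_hold)), 1e-9)
    expect_equal(mean(f_hold), 2 * (ph$target_sl[k] - 2.2), tolerance = 1e-6)
  }

  # SLS step example: k_el = 1, arm (1, 2 s), step 1 um in 1 s + 10 s hold
  m1 <- viscoelastic_model(1, data.frame(k = 1, tau = 2),
                           baseline_fraction = 0, noise_sd = 0)
  tr1 <- gen_ramp_hold_trace(m1, data.frame(delta_sl_um = 1, speed_um_s = 1,
                                            hold_s = 10), seed = 1)
  # closed form at end of hold: 1 + 2(1 - e^(-1/2)) e^(-10/2)
  expect_equal(tail(tr1$force, 1), 1 + 2 * (1 - exp(-0.5)) * exp(-5),
               tolerance = 0.01)

  # titin_fraction 0 with baseline 0.5 halves the titin_fraction 1 trace
  mk <- function(tf) viscoelastic_model(1, data.frame(k = 1, tau = 2),
                                        titin_fraction = tf,
                                        baseline_fraction = 0.5, noise_sd = 0)
  f1 <- gen_ramp_hold_trace(mk(1), default_ramp_protocol(n_steps = 2), seed = 1)$force
  f0 <- gen_ramp_hold_trace(mk(0), default_ramp_protocol(n_steps = 2), seed = 1)$force
  expect_equal(f0, f1 / 2, tolerance = 1e-12)

  expect_error(gen_ramp_hold_trace(m1, data.frame(delta_sl_um = 1,
                                                  speed_um_s = 0, hold_s = 1)),
               "speed")
  expect_error(gen_ramp_hold_trace(m1, data.frame(delta_sl_um = 1,
                                                  speed_um_s = 1, hold_s = -1)),
               "hold")
})

test_that("indentation curves follow the Hertz form exactly", {
  spec <- hertz_curve_spec(4.81, 0.5, 5, contact_offset_nm = 500,
                           max_force_nn = 3, noise_sd_nn = 0)
  cv <- gen_indentation_curve(spec, seed = 1)
  # force zero before/at contact
  expect_true(all(cv$force_nn[cv$position_nm <= 500] == 0))
  # closed-form inversion: delta at 3 nN
  cpre <- (4 / 3) * (4.81e-6 / (1 - 0.25)) * sqrt(5000)
  delta3 <- (3 / cpre)^(2 / 3)
  expect_equal(delta3, 291, tolerance = 0.01)
  expect_equal(max(cv$position_nm) - 500, delta3, tolerance = 0.01)
  # doubling E doubles force at matched positions past contact
  cv2 <- gen_indentation_curve(hertz_curve_spec(2 * 4.81, 0.5, 5,
                                                contact_offset_nm = 500,
                                                max_force_nn = 3), seed = 1)
  n <- nrow(cv2)
  expect_equal(cv2$force_nn[1:n], 2 * cv$force_nn[1:n], tolerance = 1e-12)

  expect_error(gen_indentation_curve(spec, z_max_nm = 600), "unreachable")
})

test_that("gel lanes integrate to the requested composition", {
  # intact-only: A-M window area ~ 0
  lane <- gen_gel_lane(lane_spec(composition = c(N2A_intact = 1)), seed = 1)
  q <- quantify_bands(lane)
  expect_lt(q$areas[["AM_fragment"]], 0.01)

  # all-zero composition: flat baseline-only profile
  lane0 <- gen_gel_lane(lane_spec(composition = c(N2A_intact = 0)), seed = 1)
  expect_lt(diff(range(lane0$intensity)), 1e-9)

  expect_error(lane_spec(band_positions = c(N2A_intact = 0.2, bogus = 0.5)),
               "unknown band")
  expect_error(lane_spec(band_positions = c(N2A_intact = 0.20,
                                            T2_Cronos = 0.21)),
               "overlap")
})
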