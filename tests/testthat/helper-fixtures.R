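# Shared fixtures, all generated in code at test time.

# Small striated EM scene (3 sarcomeres, 8 nm/px) used across tests.
fixture_em <- function(waviness = 0, jitter = 0, seed = 2, noise = 0.02,
                       nm_per_px = 8, height_px = 150, n_sarcomeres = 3) {
  gen_em_micrograph(sl_um = 3.0, n_sarcomeres = n_sarcomeres,
                    nm_per_px = nm_per_px, height_px = height_px,
                    waviness_amplitude_nm = waviness,
                    angle_jitter_deg = jitter, noise_sd = noise, seed = seed)
}

# Hand-rendered image with vertical dark lines of given column positions
# (px) and row spans; background 1.
fixture_lines_image <- function(cols_px, row_spans, nrow_px = 120,
                                ncol_px = 200, nm_per_px = 8, depth = 0.6,
                                sigma_px = 2) {
  img <- matrix(1, nrow_px, ncol_px)
  for (k in seq_along(cols_px)) {
    rows <- row_spans[[k]][1]:row_spans[[k]][2]
    for (j in seq_len(ncol_px)) {
      d <- j - cols_px[k]
      if (abs(d) <= 3 * sigma_px)
        img[rows, j] <- img[rows, j] - depth * exp(-0.5 * (d / sigma_px)^2)
    }
  }
  micrograph(img, nm_per_px, "EM")
}

# Independent brute-force recomputation of the fracture-area formula
# from fitted segments (used as the oracle; intentionally written
# differently from the package implementation).
oracle_fracture_area <- function(segments, theta_ref = 45) {
  ang <- sapply(segments, `[[`, "angle_deg")
  len <- sapply(segments, `[[`, "length_nm")
  msr <- sapply(segments, function(s) mean(s$residuals_nm^2))
  # length-weighted axial mean via doubled-angle vector average
  th2 <- 2 * ang * pi / 180
  ref <- atan2(sum(len * sin(th2)), sum(len * cos(th2))) / 2 * 180 / pi
  dth <- ang - ref
  dth <- ((dth + 90) %% 180) - 90
  w <- 1 + abs(dth) / theta_ref
  sum(len * msr * w) / sum(len)
}

# Independent piecewise-analytic SLS/generalized-Maxwell response at the
# hold ends, for the default ramp protocol (oracle for decomposition).
oracle_sls_steps <- function(k_el, k_m, tau, n_steps = 6, d = 0.2, v = 0.2,
                             hold = 10) {
  t_ramp <- d / v
  arm <- 0
  out <- data.frame(sl = numeric(), peak = numeric(), elastic = numeric())
  sl <- 2.2
  for (i in seq_len(n_steps)) {
    arm <- arm * exp(-t_ramp / tau) + k_m * v * tau * (1 - exp(-t_ramp / tau))
    sl <- sl + d
    peak <- k_el * (sl - 2.2) + arm
    arm_end <- arm * exp(-hold / tau)
    # elastic estimator: mean of the arm force over the final 1 s window
    tt <- seq(hold - 1, hold, by = 0.001)
    arm_win <- mean(arm * exp(-tt / tau))
    elastic <- k_el * (sl - 2.2) + arm_win
    out <- rbind(out, data.frame(sl = sl, peak = peak, elastic = elastic))
    arm <- arm_end
  }
  out
}

# Match detections to ground truth within tol_nm; returns matched count.
match_particles <- function(det, truth, tol_nm = 10) {
  if (nrow(det) == 0) return(0)
  sum(vapply(seq_len(nrow(det)), function(i) {
    min(sqrt((truth$x_nm - det$x_nm[i])^2 +
             (truth$y_nm - det$y_nm[i])^2)) <= tol_nm
  }, logical(1)))
}
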