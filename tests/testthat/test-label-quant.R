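# Immunogold particle detection, ROI filtering, distances, counts,
# filament lengths, and IF intensity ratios.

test_that("particle detection has high recall/precision on clean fields", {
  em <- fixture_em(seed = 1, noise = 0)
  n_true <- 0; n_det <- 0; n_match <- 0
  for (s in 1:4) {
    pf <- gen_particle_field(em$truth, "N2A", 4, diameter_mean_nm = 14,
                             diameter_sd_nm = 2, placement_sd_nm = 15,
                             background_rate = 0, nm_per_px = 2,
                             height_px = 400, noise_sd = 0.01, seed = s)
    det <- detect_particles(pf$image)
    n_true <- n_true + nrow(pf$truth)
    n_det <- n_det + nrow(det)
    n_match <- n_match + match_particles(det, pf$truth)
  }
  expect_gte(n_true, 50)
  expect_gte(n_match / n_true, 0.95)  # recall
  expect_gte(n_match / n_det, 0.95)   # precision
})

test_that("detection enforces the size gate, splits pairs, is scale invariant", {
  em <- fixture_em(seed = 1, n_sarcomeres = 2, height_px = 100)
  # all-6-nm field: nothing passes the 8 nm minimum
  pf6 <- gen_particle_field(em$truth, "N2A", 6, diameter_mean_nm = 6,
                            diameter_sd_nm = 0.01, nm_per_px = 2,
                            height_px = 200, noise_sd = 0, seed = 3)
  expect_equal(nrow(detect_particles(pf6$image, min_diameter_nm = 8)), 0)

  # two particles 1.5 diameters apart resolve as 2 detections
  mkpair <- function(sep_nm) {
    n <- 60; nmpp <- 2
    img <- matrix(1, n, n)
    xc <- (seq_len(n) - 0.5) * nmpp
    for (cx in c(60 - sep_nm / 2, 60 + sep_nm / 2)) {
      d <- sqrt(outer((xc - 60)^2, rep(1, n)) + outer(rep(1, n), (xc - cx)^2))
      cov <- pmin(pmax((7 - d) / nmpp + 0.5, 0), 1)
      img <- img * (1 - 0.85 * cov)
    }
    micrograph(img, nmpp, "IEM")
  }
  det <- detect_particles(mkpair(1.5 * 14))
  expect_equal(nrow(det), 2)

  # intensity-scale invariance
  im <- mkpair(1.5 * 14)
  im2 <- micrograph(im$pixels * 7, im$nm_per_px, "IEM")
  expect_equal(nrow(detect_particles(im2)), nrow(det))
  expect_equal(detect_particles(im2)$x_nm, det$x_nm, tolerance = 1e-9)

  expect_equal(nrow(detect_particles(micrograph(matrix(0.5, 50, 50), 2, "IEM"))), 0)
})

test_that("I-band ROI filtering follows the geometry and is idempotent", {
  zx <- c(1000, 4000)
  ps <- data.frame(
    x_nm = c(1000, 2500, 1850, 4010),  # on-Z, M-band, inside I/A junction + margin, near Z
    y_nm = c(100, 100, 100, 100),
    diameter_nm = rep(12, 4), fused = FALSE)
  class(ps) <- c("particle_set", "data.frame")
  out <- apply_iband_roi(ps, zx, sl_um = 3.0, aband_length_nm = 1600,
                         margin_nm = 20)
  # I-band half width = (3000 - 1600)/2 = 700, limit 720
  expect_true(out$included[1])   # exactly on a Z-disk
  expect_false(out$included[2])  # mid-A-band
  expect_false(out$included[3])  # 850 nm from Z: beyond the I/A junction
  expect_true(out$included[4])
  # idempotent
  out2 <- apply_iband_roi(out, zx, 3.0, 1600, 20)
  expect_identical(out2$included, out$included)
  expect_error(apply_iband_roi(ps, NULL, 3.0), "geometry")
})

test_that("background exclusion matches the geometric expectation", {
  em <- fixture_em(seed = 1)
  gt <- em$truth
  excl <- 0; tot <- 0
  for (s in 1:6) {
    pf <- gen_particle_field(gt, "T12", 0, background_rate = 25,
                             nm_per_px = 4, height_px = 200, seed = s)
    ps <- pf$truth
    class(ps) <- c("particle_set", "data.frame")
    out <- apply_iband_roi(ps, gt$zdisk_x_nm, gt$sl_um, gt$aband_length_nm, 20)
    excl <- excl + sum(!out$included)
    tot <- tot + nrow(out)
  }
  # expected exclusion fraction = 1 - ROI width fraction of the image
  lim <- (gt$sl_um * 1000 - gt$aband_length_nm) / 2 + 20
  roi_nm <- sum(pmin(gt$zdisk_x_nm + lim, gt$width_nm) -
                pmax(gt$zdisk_x_nm - lim, 0))
  p_excl <- 1 - roi_nm / gt$width_nm
  sem <- sqrt(p_excl * (1 - p_excl) / tot)
  expect_lt(abs(excl / tot - p_excl), 3 * sem + 1e-9)
})

test_that("epitope distances use the nearest Z-disk and recover mixtures", {
  ps <- data.frame(x_nm = 1100, y_nm = 50, diameter_nm = 12, fused = FALSE)
  class(ps) <- c("particle_set", "data.frame")
  ed <- epitope_distances(ps, c(1000, 4300), mixture = FALSE)
  expect_equal(ed$distances_nm, 100)

  # all particles on Z-disk centers -> all distances 0
  ps0 <- data.frame(x_nm = c(1000, 4300), y_nm = c(1, 2),
                    diameter_nm = 12, fused = FALSE)
  class(ps0) <- c("particle_set", "data.frame")
  expect_equal(epitope_distances(ps0, c(1000, 4300),
                                 mixture = FALSE)$distances_nm, c(0, 0))

  # recoil mixture recovery: modes within 25 nm, weights within 0.1
  em <- fixture_em(seed = 1)
  gt <- em$truth; gt$epitope_offsets_nm["HaloTag"] <- 700
  pf <- gen_particle_field(gt, "HaloTag", 60, recoil_fraction = 0.5,
                           recoil_offset_nm = 50, placement_sd_nm = 20,
                           seed = 4)
  ps2 <- pf$truth
  class(ps2) <- c("particle_set", "data.frame")
  ed2 <- epitope_distances(ps2, attr(pf$truth, "zdisk_x_nm"))
  expect_lt(abs(ed2$mixture$means[1] - 50), 25)
  expect_lt(abs(ed2$mixture$means[2] - 700), 25)
  expect_lt(abs(ed2$mixture$weights[1] - 0.5), 0.1)
})

test_that("per-sarcomere counts and group percent ratios behave", {
  # printed worked example: 34.42 of 93.60 -> 36.8%
  expect_equal(group_ratio_percent(34.42, 93.60), 36.8, tolerance = 0.005)

  b <- data.frame(start_nm = c(0, 3000, 6000), end_nm = c(3000, 6000, 9000))
  empty <- data.frame(x_nm = numeric(), y_nm = numeric(),
                      diameter_nm = numeric(), fused = logical())
  class(empty) <- c("particle_set", "data.frame")
  expect_equal(particles_per_sarcomere(empty, b)$counts, c(0, 0, 0))

  # Poisson recovery: mean within 2 SEM of the generator rate
  em <- gen_em_micrograph(sl_um = 3.0, n_sarcomeres = 10, nm_per_px = 8,
                          height_px = 80, seed = 1)
  counts <- numeric(0)
  for (s in 1:5) {
    pf <- gen_particle_field(em$truth, "HaloTag", 34.42 / 2,
                             placement_sd_nm = 30, seed = s)
    bb <- data.frame(start_nm = em$truth$zdisk_x_nm[1:10],
                     end_nm = em$truth$zdisk_x_nm[2:11])
    ps <- pf$truth; class(ps) <- c("particle_set", "data.frame")
    counts <- c(counts, particles_per_sarcomere(ps, bb)$counts)
  }
  sem <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 34.42), 2 * sem + 1e-9)

  expect_error(particles_per_sarcomere(empty,
    data.frame(start_nm = c(0, 1000), end_nm = c(2000, 3000))), "overlap")
})

test_that("thick-filament lengths pair HaloTag labels across the A-band", {
  # two labels straddling an A-band center at +/- 800 nm, same row
  ps <- data.frame(x_nm = c(1200, 2800), y_nm = c(50, 55),
                   diameter_nm = 12, fused = FALSE)
  class(ps) <- c("particle_set", "data.frame")
  fl <- thick_filament_lengths(ps, aband_centers_nm = 2000, sl_um = 3.6)
  expect_equal(fl$lengths_nm, 1600)

  # transverse offset beyond the gate: not paired in per-filament mode
  ps2 <- ps; ps2$y_nm <- c(50, 120)
  expect_warning(
    fl2 <- thick_filament_lengths(ps2, 2000, 3.6, mode = "per-filament",
                                  transverse_gate_nm = 20),
    "no label pairs")
  expect_length(fl2$lengths_nm, 0)
  # ... but paired in perpendicular-line mode
  fl3 <- thick_filament_lengths(ps2, 2000, 3.6, mode = "perpendicular-line")
  expect_equal(fl3$lengths_nm, 1600)

  # one-flank labels: empty set with warning
  ps3 <- ps[1, , drop = FALSE]
  expect_warning(fl4 <- thick_filament_lengths(ps3, 2000, 3.6), "no label pairs")
  expect_length(fl4$lengths_nm, 0)

  # generator recovery: mean within 5% across varied A-band lengths
  true_l <- c(1000, 1300, 1600)
  rec <- vapply(seq_along(true_l), function(i) {
    em <- gen_em_micrograph(sl_um = 3.0, n_sarcomeres = 3, nm_per_px = 8,
                            height_px = 150, aband_length_nm = true_l[i],
                            seed = i)
    pf <- gen_particle_field(em$truth, "HaloTag", 8, placement_sd_nm = 10,
                             nm_per_px = 4, height_px = 300, seed = i + 10)
    ab <- (em$truth$zdisk_x_nm[-4] + em$truth$zdisk_x_nm[-1]) / 2
    ps <- pf$truth; class(ps) <- c("particle_set", "data.frame")
    thick_filament_lengths(ps, ab, 3.0, mode = "perpendicular-line")$mean_nm
  }, numeric(1))
  expect_equal(rec, true_l, tolerance = 0.05)
})

test_that("IF intensity ratios recover the generating ratio and printed example", {
  # printed worked example: 32.08 of 55.95 -> 57.3%
  expect_equal(group_ratio_percent(32.08, 55.95), 57.3, tolerance = 0.01)

  em <- gen_em_micrograph(sl_um = 3.0, n_sarcomeres = 5, nm_per_px = 8,
                          height_px = 60, seed = 1)
  ch <- gen_if_channels(em$truth, ratio = 0.5, noise_sd = 0.002, seed = 2)
  r <- if_intensity_ratio(ch$halotag, ch$actn2, ch$boundaries)
  expect_equal(r$mean, 0.5, tolerance = 0.04)

  # HaloTag channel all zeros -> ratios 0
  zero <- micrograph(matrix(0, nrow(ch$halotag$pixels),
                            ncol(ch$halotag$pixels)), ch$halotag$nm_per_px, "IF")
  r0 <- if_intensity_ratio(zero, ch$actn2, ch$boundaries,
                           background = c(0, 0.05))
  expect_true(all(r0$per_sarcomere$ratio == 0))

  expect_error(if_intensity_ratio(zero,
    micrograph(matrix(1, 2, 2), 50, "IF"), ch$boundaries), "same shape")
})
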