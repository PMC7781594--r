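# Synthetic electron-micrograph generator with exact ground truth.
#
# Geometry convention: fiber long axis runs along image columns (x);
# Z-disks are near-vertical dark bands. A Z-disk centerline is, per image
# row y, x(y) = x0 + tan(theta) * (y - yc) + w(y), where theta is the
# per-disk angular jitter from vertical and w(y) the transverse
# perturbation (sinusoid or smoothed random walk).

#' Default titin epitope offsets from the Z-disk center
#'
#' Nominal axial distances (nm) of antibody epitopes from the Z-disk
#' center for a given sarcomere length and thick-filament length: T12
#' sits at the Z-disk periphery, N2A/N2B in the central I-band, PEVK near
#' the A-band edge, and the HaloTag at the I/A junction.
#'
#' @param sl_um sarcomere length, um.
#' @param aband_length_nm thick-filament (A-band) length, nm.
#' @return named numeric vector of offsets in nm.
#' @export
default_epitope_offsets <- function(sl_um, aband_length_nm = 1600) {
  ihalf <- (sl_um * 1000 - aband_length_nm) / 2
  c(T12 = 50, N2A = 0.5 * ihalf, N2B = 0.5 * ihalf,
    PEVK = 0.85 * ihalf, HaloTag = ihalf)
}

#' Generate a synthetic sarcomere electron micrograph
#'
#' Renders `n_sarcomeres` sarcomeres at sarcomere length `sl_um` as dark
#' transverse Z-disk bands plus darker A-band rectangles on a bright
#' background, with controllable per-Z-disk waviness and angular jitter,
#' and returns the exact generating geometry as ground truth.
#'
#' @param sl_um sarcomere length, um (in `[1.8, 3.6]`).
#' @param n_sarcomeres number of sarcomeres along the fiber axis.
#' @param nm_per_px pixel calibration, nm (> 0).
#' @param height_px image height in pixels.
#' @param zdisk_width_nm full width of the dark Z-disk band, nm.
#' @param aband_length_nm A-band length, nm (must not exceed the SL).
#' @param waviness_amplitude_nm transverse perturbation amplitude, nm.
#'   For `waviness_mode = "sinusoid"` this is the peak amplitude (RMS =
#'   amplitude / sqrt(2)); for `"randomwalk"` it is the RMS about the
#'   best-fit line.
#' @param waviness_mode `"sinusoid"` or `"randomwalk"`.
#' @param waviness_period_nm sinusoid period, nm (default: one full
#'   period per image height, rounded to an integer count).
#' @param angle_jitter_deg SD of the per-Z-disk orientation jitter about
#'   vertical, degrees.
#' @param zdisk_contrast,aband_contrast intensity drop of Z-disks and
#'   A-bands below the background (background = 1).
#' @param noise_sd additive Gaussian intensity noise SD (fraction of the
#'   unit dynamic range).
#' @param margin_nm blank margin left of the first and right of the last
#'   Z-disk, nm.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return list with elements `image` (a [micrograph], modality `"EM"`)
#'   and `truth` (class `sarcomere_ground_truth`): `sl_um`,
#'   `zdisk_paths` (list of n+1 two-column matrices, x_nm/y_nm per row),
#'   `zdisk_angles_deg`, `waviness_amplitude_nm`, `aband_length_nm`,
#'   `epitope_offsets_nm`, `zdisk_x_nm` (nominal Z-disk axial centers).
#' @export
gen_em_micrograph <- function(sl_um = 3.3, n_sarcomeres = 4, nm_per_px = 4,
                              height_px = 200, zdisk_width_nm = 80,
                              aband_length_nm = 1600,
                              waviness_amplitude_nm = 0,
                              waviness_mode = c("sinusoid", "randomwalk"),
                              waviness_period_nm = NULL,
                              angle_jitter_deg = 0,
                              zdisk_contrast = 0.6, aband_contrast = 0.25,
                              noise_sd = 0.05, margin_nm = 400, seed = 1) {
  waviness_mode <- match.arg(waviness_mode)
  if (nm_per_px <= 0) stop("nm_per_px must be > 0")
  if (sl_um < 1.8 || sl_um > 3.6) stop("sl_um must be in [1.8, 3.6]")
  if (aband_length_nm > sl_um * 1000)
    stop("aband_length_nm must not exceed the sarcomere length")
  if (waviness_amplitude_nm < 0) stop("waviness amplitude must be >= 0")
  iband_width_nm <- sl_um * 1000 - aband_length_nm
  if (waviness_amplitude_nm > iband_width_nm / 2)
    stop("waviness amplitude exceeds half the I-band width (Z-disks would overlap A-bands)")
  if (n_sarcomeres < 1) stop("need at least 1 sarcomere")

  set.seed(seed)
  sl_nm <- sl_um * 1000
  n_z <- n_sarcomeres + 1L
  width_px <- ceiling((n_sarcomeres * sl_nm + 2 * margin_nm) / nm_per_px)
  h <- as.integer(height_px)
  y_nm <- (seq_len(h) - 0.5) * nm_per_px
  yc <- mean(y_nm)
  height_nm <- h * nm_per_px

  if (is.null(waviness_period_nm))
    waviness_period_nm <- height_nm  # one full period over the height

  # Draw all stochastic ingredients up front as standard deviates and
  # scale them by the requested magnitudes: images generated with the
  # same seed but different waviness amplitude or angular jitter are
  # then matched scenes (identical phases/shapes, scaled perturbations).
  angles <- angle_jitter_deg * stats::rnorm(n_z)
  phases <- stats::runif(n_z, 0, 2 * pi)
  rw_draws <- matrix(stats::rnorm(h * n_z), h, n_z)
  zdisk_x0 <- margin_nm + (seq_len(n_z) - 1L) * sl_nm

  paths <- vector("list", n_z)
  for (zi in seq_len(n_z)) {
    if (waviness_amplitude_nm == 0) {
      w <- rep(0, h)
    } else if (waviness_mode == "sinusoid") {
      w <- waviness_amplitude_nm *
        sin(2 * pi * y_nm / waviness_period_nm + phases[zi])
    } else {
      rw <- cumsum(rw_draws[, zi])
      k <- stats::dnorm(seq(-15, 15), sd = 5); k <- k / sum(k)
      rw <- as.vector(conv_rows(matrix(rw, 1), k))
      # detrend (linear in y) and rescale to the requested RMS
      res <- stats::resid(stats::lm(rw ~ y_nm))
      rms <- sqrt(mean(res^2))
      w <- if (rms > 0) res / rms * waviness_amplitude_nm else res
    }
    x <- zdisk_x0[zi] + tan(angles[zi] * pi / 180) * (y_nm - yc) + w
    paths[[zi]] <- cbind(x_nm = x, y_nm = y_nm)
  }

  img <- matrix(1, h, width_px)
  x_nm_cols <- (seq_len(width_px) - 0.5) * nm_per_px
  half_w <- zdisk_width_nm / 2
  # Z-disk bands: Gaussian cross-section around the centerline, per row
  sigma_band <- half_w / 2
  for (zi in seq_len(n_z)) {
    cx <- paths[[zi]][, 1L]
    for (i in seq_len(h)) {
      j0 <- max(1L, floor((cx[i] - 3 * half_w) / nm_per_px))
      j1 <- min(width_px, ceiling((cx[i] + 3 * half_w) / nm_per_px))
      if (j0 > j1) next
      d <- x_nm_cols[j0:j1] - cx[i]
      img[i, j0:j1] <- img[i, j0:j1] -
        zdisk_contrast * exp(-0.5 * (d / sigma_band)^2)
    }
  }
  # A-bands: uniform darker rectangles centered between Z-disk pairs
  for (si in seq_len(n_sarcomeres)) {
    cx <- (zdisk_x0[si] + zdisk_x0[si + 1L]) / 2
    j0 <- max(1L, round((cx - aband_length_nm / 2) / nm_per_px))
    j1 <- min(width_px, round((cx + aband_length_nm / 2) / nm_per_px))
    img[, j0:j1] <- img[, j0:j1] - aband_contrast
  }
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  img <- pmin(pmax(img, 0), 1.2)

  truth <- structure(list(
    sl_um = sl_um,
    zdisk_paths = paths,
    zdisk_angles_deg = angles,
    waviness_amplitude_nm = waviness_amplitude_nm,
    aband_length_nm = aband_length_nm,
    epitope_offsets_nm = default_epitope_offsets(sl_um, aband_length_nm),
    zdisk_x_nm = zdisk_x0,
    height_nm = height_nm,
    width_nm = width_px * nm_per_px
  ), class = "sarcomere_ground_truth")

  list(image = micrograph(img, nm_per_px, "EM"), truth = truth)
}

#' Generate co-registered HaloTag/ACTN2 immunofluorescence channels
#'
#' ACTN2 stains the Z-disks (single bands); HaloTag stains the I/A
#' junctions (the signature doublet flanking each Z-disk region at the
#' epitope offset). Band intensities are Gaussian along the fiber axis;
#' the HaloTag integrated intensity per sarcomere is `ratio` times the
#' ACTN2 integrated intensity.
#'
#' @param gt `sarcomere_ground_truth` from [gen_em_micrograph()].
#' @param ratio true HaloTag/ACTN2 integrated intensity ratio.
#' @param band_sd_nm Gaussian axial width of the stains, nm.
#' @param nm_per_px pixel calibration.
#' @param height_px image height, px.
#' @param noise_sd additive intensity noise SD.
#' @param background constant background level added to both channels.
#' @param seed integer RNG seed.
#' @return list `halotag`, `actn2` (both [micrograph]s, modality
#'   `"IF"`), `boundaries` (sarcomere strips data.frame), `ratio`.
#' @export
gen_if_channels <- function(gt, ratio = 0.5, band_sd_nm = 150, nm_per_px = 50,
                            height_px = 40, noise_sd = 0, background = 0.05,
                            seed = 1) {
  set.seed(seed)
  w_px <- ceiling(gt$width_nm / nm_per_px)
  x_nm <- (seq_len(w_px) - 0.5) * nm_per_px
  zx <- gt$zdisk_x_nm
  halo_off <- gt$epitope_offsets_nm[["HaloTag"]]
  actn2_1d <- rep(0, w_px); halo_1d <- rep(0, w_px)
  g <- function(mu) exp(-0.5 * ((x_nm - mu) / band_sd_nm)^2)  # unit peak
  for (z in zx) {
    actn2_1d <- actn2_1d + g(z)
    halo_1d <- halo_1d + ratio / 2 * (g(z - halo_off) + g(z + halo_off))
  }
  mk <- function(v) {
    m <- matrix(rep(v, each = height_px), height_px, w_px) + background
    if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
    micrograph(pmax(m, 0), nm_per_px, "IF")
  }
  sl_nm <- gt$sl_um * 1000
  boundaries <- data.frame(start_nm = zx[-length(zx)] - 0, end_nm = zx[-1])
  # centre strips on sarcomeres (Z-disk to Z-disk)
  list(halotag = mk(halo_1d), actn2 = mk(actn2_1d),
       boundaries = boundaries, ratio = ratio)
}
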