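# Synthetic immunogold particle fields keyed to sarcomere ground truth.

#' Generate a synthetic immuno-EM particle field
#'
#' Places nanogold particles at an epitope-specific axial offset from
#' each Z-disk (both flanks), with optional placement noise, a "recoil"
#' mixture in which a fraction of particles relocates to a Z-disk
#' proximal offset (emulating elastic recoil of cleaved titin), and
#' uniform background labeling. Particles are rendered as dark discs on
#' a bright field; silver-enhancement size variability is modeled by
#' log-normal diameters.
#'
#' @param gt `sarcomere_ground_truth` from [gen_em_micrograph()].
#' @param epitope epitope name; must be in `gt$epitope_offsets_nm`.
#' @param particles_per_half_sarcomere Poisson mean label count per
#'   half-sarcomere.
#' @param diameter_mean_nm,diameter_sd_nm mean and SD of the particle
#'   diameter distribution (log-normal), nm.
#' @param background_rate expected number of background (extrasarcomeric)
#'   particles per sarcomere, placed uniformly over the image.
#' @param recoil_fraction fraction of specific labels displaced to
#'   `recoil_offset_nm` (in `[0, 1]`).
#' @param recoil_offset_nm Z-disk-proximal offset of recoiled labels, nm.
#' @param placement_sd_nm axial placement noise SD, nm.
#' @param nm_per_px pixel calibration of the rendered image.
#' @param height_px image height, px.
#' @param noise_sd additive image noise SD.
#' @param seed integer RNG seed.
#' @return list with `image` (a [micrograph], modality `"IEM"`) and
#'   `truth`: data.frame `x_nm, y_nm, diameter_nm, is_background,
#'   recoiled, sarcomere` plus attribute `zdisk_x_nm`.
#' @export
gen_particle_field <- function(gt, epitope,
                               particles_per_half_sarcomere = 10,
                               diameter_mean_nm = 14, diameter_sd_nm = 3,
                               background_rate = 0,
                               recoil_fraction = 0, recoil_offset_nm = 50,
                               placement_sd_nm = 0,
                               nm_per_px = 4, height_px = 200,
                               noise_sd = 0.02, seed = 1) {
  if (!epitope %in% names(gt$epitope_offsets_nm))
    stop("unknown epitope: ", epitope)
  if (particles_per_half_sarcomere < 0 || background_rate < 0)
    stop("rates must be >= 0")
  if (recoil_fraction < 0 || recoil_fraction > 1)
    stop("recoil_fraction must be in [0, 1]")
  set.seed(seed)

  offset <- gt$epitope_offsets_nm[[epitope]]
  zx <- gt$zdisk_x_nm
  n_z <- length(zx)
  n_sarc <- n_z - 1L
  width_nm <- gt$width_nm
  height_nm <- height_px * nm_per_px

  rows <- list()
  # specific labels: per Z-disk flank facing into a sarcomere
  for (zi in seq_len(n_z)) {
    for (side in c(-1, 1)) {
      sarc <- if (side < 0) zi - 1L else zi
      if (sarc < 1L || sarc > n_sarc) next
      n <- stats::rpois(1, particles_per_half_sarcomere)
      if (n == 0) next
      recoiled <- stats::runif(n) < recoil_fraction
      off <- ifelse(recoiled, recoil_offset_nm, offset)
      x <- zx[zi] + side * (off + stats::rnorm(n, 0, placement_sd_nm))
      y <- stats::runif(n, 0, height_nm)
      rows[[length(rows) + 1L]] <- data.frame(
        x_nm = x, y_nm = y, is_background = FALSE,
        recoiled = recoiled, sarcomere = sarc)
    }
  }
  # background labels, uniform over the image
  n_bg <- stats::rpois(1, background_rate * n_sarc)
  if (n_bg > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      x_nm = stats::runif(n_bg, 0, width_nm),
      y_nm = stats::runif(n_bg, 0, height_nm),
      is_background = TRUE, recoiled = FALSE, sarcomere = NA_integer_)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_nm = numeric(), y_nm = numeric(), is_background = logical(),
               recoiled = logical(), sarcomere = integer())
  # log-normal diameters with the requested mean/SD
  if (nrow(truth) > 0) {
    cv2 <- (diameter_sd_nm / diameter_mean_nm)^2
    sdlog <- sqrt(log(1 + cv2))
    meanlog <- log(diameter_mean_nm) - sdlog^2 / 2
    truth$diameter_nm <- stats::rlnorm(nrow(truth), meanlog, sdlog)
    truth <- truth[truth$x_nm > 0 & truth$x_nm < width_nm, , drop = FALSE]
  } else truth$diameter_nm <- numeric()
  truth <- truth[, c("x_nm", "y_nm", "diameter_nm", "is_background",
                     "recoiled", "sarcomere")]

  # render: bright field, particles as dark discs with sub-pixel centers
  w_px <- ceiling(width_nm / nm_per_px)
  img <- matrix(1, height_px, w_px)
  if (nrow(truth) > 0) {
    xc_cols <- (seq_len(w_px) - 0.5) * nm_per_px
    yc_rows <- (seq_len(height_px) - 0.5) * nm_per_px
    for (p in seq_len(nrow(truth))) {
      r <- truth$diameter_nm[p] / 2
      i0 <- max(1L, floor((truth$y_nm[p] - r - nm_per_px) / nm_per_px))
      i1 <- min(height_px, ceiling((truth$y_nm[p] + r + nm_per_px) / nm_per_px))
      j0 <- max(1L, floor((truth$x_nm[p] - r - nm_per_px) / nm_per_px))
      j1 <- min(w_px, ceiling((truth$x_nm[p] + r + nm_per_px) / nm_per_px))
      if (i0 > i1 || j0 > j1) next
      dx <- outer(rep(1, i1 - i0 + 1L), xc_cols[j0:j1] - truth$x_nm[p])
      dy <- outer(yc_rows[i0:i1] - truth$y_nm[p], rep(1, j1 - j0 + 1L))
      d <- sqrt(dx^2 + dy^2)
      # soft-edged disc (half-pixel antialiasing)
      cov <- pmin(pmax((r - d) / nm_per_px + 0.5, 0), 1)
      img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] * (1 - 0.85 * cov)
    }
  }
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  img <- pmin(pmax(img, 0), 1.2)

  attr(truth, "zdisk_x_nm") <- zx
  attr(truth, "epitope") <- epitope
  list(image = micrograph(img, nm_per_px, "IEM"), truth = truth)
}
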