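#' Calibrated micrograph container
#'
#' A 2-D grayscale intensity raster with physical calibration. Rows run
#' top to bottom, columns left to right; the fiber long axis is assumed
#' horizontal (along columns) throughout the package.
#'
#' @param pixels numeric matrix of non-negative, finite intensities.
#' @param nm_per_px pixel size in nanometres (> 0).
#' @param modality one of `"EM"`, `"IEM"`, `"IF"`.
#' @return object of class `micrograph`.
#' @export
micrograph <- function(pixels, nm_per_px, modality = c("EM", "IEM", "IF")) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("`pixels` must be finite and non-negative")
  if (!is.numeric(nm_per_px) || length(nm_per_px) != 1L || nm_per_px <= 0)
    stop("`nm_per_px` must be a positive scalar")
  structure(list(pixels = pixels, nm_per_px = nm_per_px, modality = modality),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph %s: %d x %d px, %.3g nm/px>\n",
              x$modality, nrow(x$pixels), ncol(x$pixels), x$nm_per_px))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' Viscoelastic fiber model specification
#'
#' Generalized Maxwell (standard-linear-solid family) model of passive
#' fiber tension: a parallel spring `k_elastic` plus up to a few Maxwell
#' arms, with the whole viscoelastic response scaled by the fraction of
#' intact titin on top of a titin-independent baseline fraction.
#'
#' Total force is `(baseline_fraction + (1 - baseline_fraction) *
#' titin_fraction) * V(t)` where `V(t)` is the full-model response, so
#' `titin_fraction = 1` reproduces the intact fiber and
#' `titin_fraction = 0` leaves the residual non-titin force.
#'
#' @param k_elastic parallel-spring stiffness (normalized force per um SL).
#' @param maxwell_arms data.frame with columns `k` (stiffness) and `tau`
#'   (relaxation time, s); may have zero rows for a pure spring.
#' @param titin_fraction fraction of intact titin in `[0, 1]`.
#' @param baseline_fraction titin-independent force fraction in `[0, 1]`.
#' @param noise_sd additive Gaussian force noise SD.
#' @param slack_sl_um slack sarcomere length (zero-force length), um.
#' @return object of class `viscoelastic_model`.
#' @export
viscoelastic_model <- function(k_elastic, maxwell_arms = data.frame(k = numeric(), tau = numeric()),
                               titin_fraction = 1, baseline_fraction = 0.5,
                               noise_sd = 0, slack_sl_um = 2.2) {
  stopifnot(is.data.frame(maxwell_arms),
            all(c("k", "tau") %in% names(maxwell_arms)))
  if (k_elastic <= 0) stop("k_elastic must be > 0")
  if (nrow(maxwell_arms) > 0 &&
      (any(maxwell_arms$k <= 0) || any(maxwell_arms$tau <= 0)))
    stop("Maxwell arm stiffnesses and time constants must be > 0")
  if (titin_fraction < 0 || titin_fraction > 1)
    stop("titin_fraction must be in [0, 1]")
  if (baseline_fraction < 0 || baseline_fraction > 1)
    stop("baseline_fraction must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(k_elastic = k_elastic, maxwell_arms = maxwell_arms,
                 titin_fraction = titin_fraction,
                 baseline_fraction = baseline_fraction,
                 noise_sd = noise_sd, slack_sl_um = slack_sl_um),
            class = "viscoelastic_model")
}

#' Hertz indentation curve specification
#'
#' Ground truth for a spherical-indenter force-distance curve:
#' `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)` past contact.
#'
#' @param E_kpa true Young's modulus, kPa (> 0).
#' @param nu Poisson ratio in `[0, 0.5]`.
#' @param R_um indenter sphere radius, um (> 0).
#' @param contact_offset_nm piezo position of true contact, nm.
#' @param max_force_nn trigger force, nN (> 0); curve truncated there.
#' @param noise_sd_nn additive force noise SD, nN.
#' @return object of class `hertz_curve_spec`.
#' @export
hertz_curve_spec <- function(E_kpa, nu = 0.5, R_um = 5, contact_offset_nm = 500,
                             max_force_nn = 3, noise_sd_nn = 0) {
  if (E_kpa <= 0) stop("E_kpa must be > 0")
  if (nu < 0 || nu > 0.5) stop("nu must be in [0, 0.5]")
  if (R_um <= 0) stop("R_um must be > 0")
  if (max_force_nn <= 0) stop("max_force_nn must be > 0")
  if (noise_sd_nn < 0) stop("noise_sd_nn must be >= 0")
  structure(list(E_kpa = E_kpa, nu = nu, R_um = R_um,
                 contact_offset_nm = contact_offset_nm,
                 max_force_nn = max_force_nn, noise_sd_nn = noise_sd_nn),
            class = "hertz_curve_spec")
}

#' Gel lane specification
#'
#' Bands are Gaussians on a relative migration axis (0 = top/large
#' species, 1 = bottom), with integrated areas proportional to
#' `composition`, on a linear baseline.
#'
#' @param band_positions named numeric: band centre on the migration axis.
#' @param band_widths named numeric: Gaussian SD per band.
#' @param composition named numeric: true area fraction per band (>= 0).
#' @param baseline_slope,baseline_intercept linear baseline parameters.
#' @param noise_sd additive intensity noise SD.
#' @return object of class `lane_spec`.
#' @export
lane_spec <- function(band_positions = c(N2A_intact = 0.20, T2_Cronos = 0.30,
                                         AM_fragment = 0.38, ZI_fragment = 0.55,
                                         NEB = 0.68, MyHC = 0.85),
                      band_widths = NULL,
                      composition = c(N2A_intact = 1),
                      baseline_slope = 0, baseline_intercept = 0.02,
                      noise_sd = 0) {
  allowed <- c("N2A_intact", "T2_Cronos", "AM_fragment", "ZI_fragment",
               "NEB", "MyHC")
  if (!all(names(band_positions) %in% allowed))
    stop("unknown band name(s): ",
         paste(setdiff(names(band_positions), allowed), collapse = ", "))
  if (is.null(band_widths))
    band_widths <- stats::setNames(rep(0.012, length(band_positions)),
                                   names(band_positions))
  if (!all(names(composition) %in% names(band_positions)))
    stop("composition names must be a subset of band_positions names")
  if (any(composition < 0)) stop("composition values must be >= 0")
  # reject overlap at 3 SD
  ord <- order(band_positions)
  p <- band_positions[ord]; w <- band_widths[names(band_positions)[ord]]
  if (length(p) > 1) {
    lo <- p[-1] - 3 * w[-1]
    hi <- p[-length(p)] + 3 * w[-length(w)]
    if (any(lo < hi)) stop("band windows overlap at 3 SD")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(band_positions = band_positions, band_widths = band_widths,
                 composition = composition, baseline_slope = baseline_slope,
                 baseline_intercept = baseline_intercept, noise_sd = noise_sd),
            class = "lane_spec")
}
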