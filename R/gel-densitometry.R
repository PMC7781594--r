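# Gel lane densitometry: profile extraction, baseline removal, band
# quantification and titin cleavage/ratio readouts.

#' Extract a lane profile from a gel image
#'
#' Mean inverted intensity across the lane width per migration row; the
#' migration axis runs down the image rows.
#'
#' @param img a [micrograph] of the gel scan.
#' @param box list or vector `row0, row1, col0, col1` (inclusive pixel
#'   bounds of the lane).
#' @return a `lane_profile` (columns `position` in `[0, 1]`,
#'   `intensity`); band windows must be supplied to [quantify_bands()].
#' @export
extract_profile <- function(img, box) {
  stopifnot(inherits(img, "micrograph"))
  box <- as.integer(unlist(box)[1:4])
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (box[1] < 1 || box[2] > nr || box[3] < 1 || box[4] > nc ||
      box[1] > box[2] || box[3] > box[4])
    stop("lane box outside the image")
  sub <- img$pixels[box[1]:box[2], box[3]:box[4], drop = FALSE]
  inten <- rowMeans(max(img$pixels) - sub)
  n <- length(inten)
  out <- data.frame(position = if (n > 1) seq(0, 1, length.out = n) else 0.5,
                    intensity = inten)
  class(out) <- c("lane_profile", "data.frame")
  out
}

# Rolling minimum with window half-width w (indices), edge-truncated,
# followed by a rolling maximum (morphological opening) so that the
# baseline hugs valleys without undercutting broad bands.
rolling_baseline <- function(x, w) {
  n <- length(x)
  w <- max(1L, as.integer(w))
  rmin <- vapply(seq_len(n), function(i)
    min(x[max(1L, i - w):min(n, i + w)]), numeric(1))
  vapply(seq_len(n), function(i)
    max(rmin[max(1L, i - w):min(n, i + w)]), numeric(1))
}

#' Quantify gel bands and titin cleavage from a lane profile
#'
#' The baseline is removed by a morphological rolling-minimum opening
#' (window default 3x the widest band window) and each named band is
#' integrated (trapezoid rule) over its window. Percent cleaved titin is
#' `100 * AM / (AM + intact)` using the A-M fragment and intact N2A
#' bands only (the T2/Cronos doublet is excluded from the denominator).
#' MyHC/titin, titin/NEB and MyHC/NEB ratios are reported when the bands
#' are present; "titin" defaults to intact + A-M + Z-I.
#'
#' @param profile a `lane_profile`; band windows are taken from its
#'   `band_windows` attribute unless supplied.
#' @param band_windows named list of `c(start, end)` on the position
#'   axis.
#' @param baseline_window rolling-minimum half-width on the position
#'   axis (default 3x the widest band window).
#' @param titin_bands band names summed as the "titin" denominator for
#'   the MyHC/titin ratio.
#' @return a `band_quant`: list `areas` (named), `percent_cleaved`,
#'   `ratios` (named list), `baseline` (numeric vector).
#' @export
quantify_bands <- function(profile, band_windows = NULL,
                           baseline_window = NULL,
                           titin_bands = c("N2A_intact", "AM_fragment",
                                           "ZI_fragment")) {
  if (is.null(band_windows)) band_windows <- attr(profile, "band_windows")
  if (is.null(band_windows) || length(band_windows) == 0)
    stop("band windows must be defined")
  pos <- profile$position; y <- profile$intensity
  dx <- stats::median(diff(pos))
  widths <- vapply(band_windows, function(w) w[2] - w[1], numeric(1))
  if (is.null(baseline_window)) baseline_window <- 3 * max(widths)
  w_idx <- round(baseline_window / dx)
  base <- rolling_baseline(y, w_idx)
  net <- y - base
  areas <- vapply(names(band_windows), function(b) {
    w <- band_windows[[b]]
    sel <- pos >= w[1] & pos <= w[2]
    if (sum(sel) < 2) return(0)
    a <- sum(diff(pos[sel]) * (utils::head(net[sel], -1) + utils::tail(net[sel], -1)) / 2)
    if (a < 0) {
      warning("negative net area for band ", b, "; clipped to 0")
      a <- 0
    }
    a
  }, numeric(1))
  pc <- NA_real_
  if (all(c("AM_fragment", "N2A_intact") %in% names(areas))) {
    denom <- areas[["AM_fragment"]] + areas[["N2A_intact"]]
    pc <- if (denom > 0) 100 * areas[["AM_fragment"]] / denom else NA_real_
  }
  ratios <- list()
  titin <- sum(areas[intersect(titin_bands, names(areas))])
  if ("MyHC" %in% names(areas) && titin > 0)
    ratios$MyHC_titin <- areas[["MyHC"]] / titin
  if (all(c("NEB") %in% names(areas)) && areas[["NEB"]] > 0) {
    if (titin > 0) ratios$titin_NEB <- titin / areas[["NEB"]]
    if ("MyHC" %in% names(areas))
      ratios$MyHC_NEB <- areas[["MyHC"]] / areas[["NEB"]]
  }
  structure(list(areas = areas, percent_cleaved = pc, ratios = ratios,
                 baseline = base),
            class = "band_quant")
}
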