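# Readers and writers for the package's standard file formats.

#' Write a micrograph as 16-bit grayscale PNG with a JSON sidecar
#'
#' Intensities are scaled to the 16-bit range; calibration and modality
#' go to `<path>.json`. Requires the `png` package.
#'
#' @param img a [micrograph].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_micrograph_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG micrographs")
  px <- img$pixels
  rng <- range(px)
  scaled <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  png::writePNG(scaled, path, dpi = 25.4e6 / img$nm_per_px)
  jsonlite::write_json(list(nm_per_px = img$nm_per_px, modality = img$modality,
                            intensity_range = rng),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a micrograph written by [write_micrograph_png()]
#'
#' @param path PNG path; `<path>.json` must exist unless `nm_per_px` is
#'   given.
#' @param nm_per_px calibration override.
#' @param modality modality override.
#' @return a [micrograph].
#' @export
read_micrograph_png <- function(path, nm_per_px = NULL, modality = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read PNG micrographs")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (is.null(nm_per_px)) nm_per_px <- meta$nm_per_px
  if (is.null(nm_per_px)) stop("no calibration: give nm_per_px or a sidecar JSON")
  if (is.null(modality)) modality <- if (!is.null(meta$modality)) meta$modality else "EM"
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  micrograph(px, as.numeric(nm_per_px), modality)
}

#' Write / read force traces, indentation curves and lane profiles
#'
#' Plain CSV with the package's canonical headers: traces use
#' `time_s, sl_um, force`; indentation curves `position_nm, force_nn`;
#' lane profiles `position, intensity`.
#'
#' @param x the object to write.
#' @param path CSV path.
#' @return `path` (writers) or the object (readers).
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_trace_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("time_s", "sl_um", "force")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "sl_um", "force") %in% names(d)))
  class(d) <- c("force_trace", "data.frame")
  d
}

#' @rdname trace_io
#' @export
write_curve_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("position_nm", "force_nn")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @param R_um probe sphere radius attached on read, um.
#' @export
read_curve_csv <- function(path, R_um = 5) {
  d <- utils::read.csv(path)
  stopifnot(all(c("position_nm", "force_nn") %in% names(d)))
  attr(d, "probe") <- list(R_um = R_um, k_c = NA_real_)
  class(d) <- c("indentation_curve", "data.frame")
  d
}

#' @rdname trace_io
#' @export
write_profile_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("position", "intensity")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("position", "intensity") %in% names(d)))
  class(d) <- c("lane_profile", "data.frame")
  d
}
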