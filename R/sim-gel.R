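# Synthetic gel lane profiles (1-D densitometry fixtures).

#' Generate a synthetic gel lane profile
#'
#' Renders each band as a Gaussian with integrated area proportional to
#' its composition entry, adds a linear baseline and optional noise.
#'
#' @param spec a [lane_spec()].
#' @param n number of samples along the migration axis.
#' @param seed integer RNG seed (noise only).
#' @return a `lane_profile`: data.frame `position, intensity` with
#'   attributes `band_windows` (named list of `c(start, end)`, center
#'   +/- 4 SD) and `truth` (named true areas).
#' @export
gen_gel_lane <- function(spec, n = 2000, seed = 1) {
  stopifnot(inherits(spec, "lane_spec"))
  set.seed(seed)
  pos <- seq(0, 1, length.out = n)
  intensity <- spec$baseline_intercept + spec$baseline_slope * pos
  areas <- stats::setNames(numeric(length(spec$band_positions)),
                           names(spec$band_positions))
  for (b in names(spec$band_positions)) {
    a <- if (b %in% names(spec$composition)) spec$composition[[b]] else 0
    areas[[b]] <- a
    if (a > 0)
      intensity <- intensity +
        a * stats::dnorm(pos, spec$band_positions[[b]], spec$band_widths[[b]])
  }
  if (spec$noise_sd > 0)
    intensity <- intensity + stats::rnorm(n, 0, spec$noise_sd)
  windows <- lapply(names(spec$band_positions), function(b)
    c(start = max(0, spec$band_positions[[b]] - 4 * spec$band_widths[[b]]),
      end = min(1, spec$band_positions[[b]] + 4 * spec$band_widths[[b]])))
  names(windows) <- names(spec$band_positions)
  out <- data.frame(position = pos, intensity = intensity)
  attr(out, "band_windows") <- windows
  attr(out, "truth") <- areas
  class(out) <- c("lane_profile", "data.frame")
  out
}
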