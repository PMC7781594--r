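# Hertz spherical-indenter analysis of AFM force-distance curves.

#' Locate the contact point of a force-distance curve
#'
#' The pre-contact baseline mean and SD are estimated from the initial
#' flat segment; the first sustained excursion above baseline + 5 SD
#' marks the rising branch, and the contact position is refined by
#' least-squares fitting `F = a * max(0, z - z0)^(3/2)` over the rise
#' with a golden-section search on `z0` (the prefactor `a` has a closed
#' form given `z0`).
#'
#' @param curve an `indentation_curve` (columns `position_nm`,
#'   `force_nn`).
#' @param baseline_frac fraction of the curve (from the start) whose
#'   minimum-variance half estimates the baseline.
#' @return list `contact_nm`, `baseline_nn`, `baseline_sd_nn`.
#' @export
find_contact_point <- function(curve, baseline_frac = 0.3) {
  z <- curve$position_nm; f <- curve$force_nn
  n <- length(z)
  if (n < 20) stop("curve too short")
  nb <- max(5L, floor(baseline_frac * n))
  b_mean <- mean(f[seq_len(nb)])
  b_sd <- stats::sd(f[seq_len(nb)])
  thr <- b_mean + 5 * max(b_sd, 1e-12)
  above <- which(f > thr)
  if (length(above) == 0)
    stop("no rising branch: force never exceeds baseline + 5 SD")
  i_rise <- above[1]
  # refine z0 over a bracket around the first crossing
  lo <- z[max(1L, i_rise - max(10L, round(0.2 * n)))]
  hi <- z[min(n, i_rise + max(5L, round(0.1 * n)))]
  fc <- f - b_mean
  sse <- function(z0) {
    d <- pmax(0, z - z0)^1.5
    s2 <- sum(d^2)
    if (s2 == 0) return(sum(fc^2))
    a <- sum(fc * d) / s2
    sum((fc - a * d)^2)
  }
  opt <- stats::optimize(sse, c(lo, hi))
  list(contact_nm = opt$minimum, baseline_nn = b_mean,
       baseline_sd_nn = max(b_sd, 0))
}

#' Fit the Hertz spherical-contact model to an indentation curve
#'
#' Fits `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)` over
#' `delta = z - contact` (optionally corrected for cantilever deflection
#' `delta = z - contact - F / k_c`), restricted to
#' `delta <= delta_max_frac * R` for Hertz small-indentation validity.
#' `E` has a closed-form least-squares solution given the contact point.
#' The indentation depth at the trigger force is interpolated on the
#' measured curve.
#'
#' @param curve an `indentation_curve`.
#' @param nu Poisson ratio (0.5 by default, incompressible tissue).
#' @param R_um sphere radius, um (default from the curve's probe
#'   attribute, else 5 um = half a 10 um bead).
#' @param contact_nm contact position; computed by
#'   [find_contact_point()] when NULL.
#' @param trigger_nn trigger force at which depth is reported, nN.
#' @param k_c cantilever spring constant, N/m; when given, positions are
#'   deflection-corrected.
#' @param delta_max_frac fit-domain cap as a fraction of R.
#' @param position_units `"nm"` (default) or `"um"`: units of the
#'   curve's position axis (and of `contact_nm` when supplied); results
#'   are always reported in nm and kPa.
#' @return a `hertz_fit`: list `E_kpa, nu, contact_nm,
#'   depth_at_trigger_nm, residual_rms_nn, fit_window_nm, n_points`.
#' @export
fit_hertz <- function(curve, nu = 0.5, R_um = NULL, contact_nm = NULL,
                      trigger_nn = 3, k_c = NULL, delta_max_frac = 0.4,
                      position_units = c("nm", "um")) {
  position_units <- match.arg(position_units)
  if (position_units == "um") {
    curve$position_nm <- curve$position_nm * 1000
    if (!is.null(contact_nm)) contact_nm <- contact_nm * 1000
  }
  if (is.null(R_um)) {
    probe <- attr(curve, "probe")
    R_um <- if (!is.null(probe) && is.finite(probe$R_um)) probe$R_um else 5
  }
  if (is.null(contact_nm)) {
    cp <- find_contact_point(curve)
    contact_nm <- cp$contact_nm
    baseline <- cp$baseline_nn
  } else baseline <- 0
  z <- curve$position_nm
  f <- curve$force_nn - baseline
  delta <- z - contact_nm
  if (!is.null(k_c)) delta <- delta - f / k_c  # k_c in N/m == nN/nm
  R_nm <- R_um * 1000
  sel <- delta > 0 & delta <= delta_max_frac * R_nm
  if (sum(sel) < 20) stop("fewer than 20 samples past contact in the fit window")
  d32 <- delta[sel]^1.5
  a <- sum(f[sel] * d32) / sum(d32^2)
  if (a <= 0) stop("negative fitted modulus: check the contact point")
  E_kpa <- a / ((4 / 3) * sqrt(R_nm) / (1 - nu^2)) * 1e6
  resid <- f[sel] - a * d32
  # depth at the trigger force, interpolated on the measured curve
  ds <- delta[sel]; fs <- f[sel]
  ord <- order(ds)
  depth <- if (max(fs) >= trigger_nn)
    stats::approx(fs[ord], ds[ord], xout = trigger_nn, ties = mean)$y
  else (trigger_nn / a)^(2 / 3)  # model inversion when the curve stops short
  structure(list(E_kpa = E_kpa, nu = nu, contact_nm = contact_nm,
                 depth_at_trigger_nm = depth,
                 residual_rms_nn = sqrt(mean(resid^2)),
                 fit_window_nm = range(ds), n_points = sum(sel)),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit: E = %.3g kPa, depth@trigger = %.3g nm, contact = %.3g nm>\n",
              x$E_kpa, x$depth_at_trigger_nm, x$contact_nm))
  invisible(x)
}

#' Summarize Hertz fits by group
#'
#' Per-group mean and SEM of depth at trigger and Young's modulus, and
#' the before/after percent changes (depth increases are reported as
#' `100 * (after - before) / before`, modulus decreases as
#' `100 * (before - after) / before`).
#'
#' @param fits list of `hertz_fit` objects.
#' @param group character vector (one per fit), e.g.
#'   `"Hom_before"`/`"Hom_after"`.
#' @param before,after group labels for the percent-change comparison
#'   (optional).
#' @return list `groups` (data.frame `group, n, depth_mean, depth_sem,
#'   E_mean, E_sem`) and, when `before`/`after` given,
#'   `depth_change_percent` and `modulus_change_percent`.
#' @export
batch_summary <- function(fits, group, before = NULL, after = NULL) {
  stopifnot(length(fits) == length(group))
  if (length(fits) == 0) stop("empty fit list")
  depth <- vapply(fits, function(x) x$depth_at_trigger_nm, numeric(1))
  E <- vapply(fits, function(x) x$E_kpa, numeric(1))
  gs <- unique(group)
  tab <- do.call(rbind, lapply(gs, function(g) {
    i <- group == g
    if (!any(i)) stop("empty group: ", g)
    data.frame(group = g, n = sum(i),
               depth_mean = mean(depth[i]),
               depth_sem = stats::sd(depth[i]) / sqrt(sum(i)),
               E_mean = mean(E[i]),
               E_sem = stats::sd(E[i]) / sqrt(sum(i)))
  }))
  out <- list(groups = tab)
  if (!is.null(before) && !is.null(after)) {
    b <- tab[tab$group == before, ]; a <- tab[tab$group == after, ]
    out$depth_change_percent <- 100 * (a$depth_mean - b$depth_mean) / b$depth_mean
    out$modulus_change_percent <- 100 * (b$E_mean - a$E_mean) / b$E_mean
  }
  out
}

#' Percent change of paired group means
#'
#' `100 * (after - before) / before` when `increase = TRUE` (e.g.
#' indentation depth), `100 * (before - after) / before` otherwise
#' (e.g. modulus loss).
#'
#' @param before,after group means.
#' @param increase report an increase (default) or a decrease.
#' @return percent scalar.
#' @export
percent_change <- function(before, after, increase = TRUE) {
  if (before <= 0) stop("before must be > 0")
  if (increase) 100 * (after - before) / before
  else 100 * (before - after) / before
}
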