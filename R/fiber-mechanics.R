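# Passive and active fiber-mechanics analysis.

# Centred boxcar smoothing; edge NAs are filled with the nearest valid
# smoothed value (so noisy raw samples never leak into derivatives).
boxcar_fill <- function(x, w) {
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  ok <- which(!is.na(sm))
  if (length(ok) == 0) return(x)
  sm[seq_len(ok[1] - 1L)] <- sm[ok[1]]
  n <- length(sm)
  last <- ok[length(ok)]
  if (last < n) sm[(last + 1L):n] <- sm[last]
  sm
}

#' Segment a ramp-hold protocol from the sarcomere-length channel
#'
#' Phases are detected from the SL derivative with a two-level
#' (hysteresis) threshold: a ramp opens when the smoothed |dSL/dt|
#' exceeds `speed_threshold_um_s` and closes when it falls below half of
#' it, which makes the segmentation robust to channel noise.
#'
#' @param trace a `force_trace` (columns `time_s`, `sl_um`, `force`).
#' @param speed_threshold_um_s ramp-detection threshold, um/s.
#' @param smooth_s derivative smoothing window, s.
#' @return data.frame `phase` (`"ramp"`, `"release"` or `"hold"`),
#'   `start`, `end` (row indices), `target_sl` (plateau SL, NA for
#'   ramps).
#' @export
segment_protocol <- function(trace, speed_threshold_um_s = 0.02,
                             smooth_s = 0.05) {
  sl <- trace$sl_um; t <- trace$time_s
  if (diff(range(sl)) == 0) stop("SL channel constant: no protocol to segment")
  dt <- stats::median(diff(t))
  w <- max(1L, round(smooth_s / dt))
  sl_s <- if (w > 1) boxcar_fill(sl, w) else sl
  # lagged central difference of the smoothed SL: slope noise shrinks as
  # the window grows, so large smooth_s makes segmentation noise-immune
  k <- max(1L, round(w / 2))
  n <- length(sl_s)
  v <- numeric(n)
  i <- (k + 1):(n - k)
  v[i] <- (sl_s[i + k] - sl_s[i - k]) / (2 * k * dt)
  hi <- speed_threshold_um_s; lo <- hi / 2
  moving <- logical(length(v))
  state <- FALSE
  av <- abs(v)
  for (i in seq_along(v)) {
    state <- if (state) av[i] > lo else av[i] > hi
    moving[i] <- state
  }
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- data.frame(phase = character(0), start = integer(0),
                    end = integer(0), target_sl = numeric(0))
  for (k in seq_along(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (r$values[k]) {
      dir <- sl[i1] - sl[i0]
      out <- rbind(out, data.frame(
        phase = if (dir >= 0) "ramp" else "release",
        start = i0, end = i1, target_sl = NA_real_))
    } else {
      out <- rbind(out, data.frame(
        phase = "hold", start = i0, end = i1,
        target_sl = stats::median(sl[i0:i1])))
    }
  }
  out
}

#' Elastic/viscous decomposition of ramp-hold force traces
#'
#' Per hold phase: the elastic (velocity-insensitive) tension is the
#' mean force over the final `hold_window_s` of the hold; the viscous
#' (velocity-sensitive) tension is the peak force over the terminal
#' `ramp_peak_frac` of the preceding ramp minus the elastic tension.
#' Elastic + viscous equals the ramp-end peak by construction.
#'
#' @param trace a `force_trace`.
#' @param phases output of [segment_protocol()]; computed if missing.
#' @param hold_window_s elastic averaging window, s.
#' @param ramp_peak_frac terminal fraction of the ramp searched for the
#'   peak (the search extends 0.25 s into the following hold so blurred
#'   phase boundaries cannot miss the true ramp-end peak).
#' @param peak_smooth_s force smoothing window for the peak estimate, s
#'   (a short boxcar; the max of raw noisy samples is upward-biased).
#' @param reference optional normalization force (e.g. the pre-treatment
#'   peak); both components are divided by it.
#' @return a `viscoelastic_summary`: data.frame `sl_um, elastic,
#'   viscous, peak` (one row per hold preceded by a ramp) with attribute
#'   `normalization_reference`.
#' @export
decompose_viscoelastic <- function(trace, phases = NULL, hold_window_s = 1,
                                   ramp_peak_frac = 0.05, reference = NULL,
                                   peak_smooth_s = 0.025) {
  if (is.null(phases)) phases <- segment_protocol(trace)
  t <- trace$time_s; f <- trace$force
  dt <- stats::median(diff(t))
  wp <- max(1L, round(peak_smooth_s / dt))
  f_s <- if (wp > 1) boxcar_fill(f, wp) else f
  rows <- list()
  for (k in seq_len(nrow(phases))) {
    if (phases$phase[k] != "hold" || k == 1L) next
    if (phases$phase[k - 1L] != "ramp") next
    h0 <- phases$start[k]; h1 <- phases$end[k]
    r0 <- phases$start[k - 1L]; r1 <- phases$end[k - 1L]
    dur <- t[h1] - t[h0]
    win <- hold_window_s
    if (dur < win) {
      warning("hold shorter than the averaging window; window shrunk to the hold")
      win <- dur
    }
    sel_h <- which(t[h0:h1] >= t[h1] - win) + h0 - 1L
    elastic <- mean(f[sel_h])
    n_r <- r1 - r0 + 1L
    r_end <- min(h1, r1 + round(0.25 / dt))
    sel_r <- (r1 - max(1L, ceiling(ramp_peak_frac * n_r)) + 1L):r_end
    peak <- max(f_s[sel_r])
    rows[[length(rows) + 1L]] <- data.frame(
      sl_um = phases$target_sl[k], elastic = elastic,
      viscous = peak - elastic, peak = peak)
  }
  if (length(rows) == 0) stop("no ramp-hold pair found")
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    out$elastic <- out$elastic / reference
    out$viscous <- out$viscous / reference
    out$peak <- out$peak / reference
  }
  attr(out, "normalization_reference") <- reference
  class(out) <- c("viscoelastic_summary", "data.frame")
  out
}

#' Normalize a protease-treatment timecourse to time-matched controls
#'
#' Treated force is divided by the time-matched mean of the control
#' traces (removing ordinary stress relaxation) and then by its own
#' value at t = 0 (the moment of protease addition), and sampled at the
#' standard time grid.
#'
#' @param treated a `force_trace` or list of traces (averaged).
#' @param controls list of control `force_trace`s (no treatment).
#' @param sample_times_min sampling grid, minutes.
#' @return a `timecourse_result`: data.frame `time_min,
#'   normalized_force` with `value at 0 == 1`.
#' @export
normalize_timecourse <- function(treated, controls,
                                 sample_times_min = c(0:5, 10, 15, 20, 25, 30)) {
  if (inherits(treated, "force_trace")) treated <- list(treated)
  if (inherits(controls, "force_trace")) controls <- list(controls)
  t_ref <- treated[[1]]$time_s
  avg <- function(traces) {
    m <- vapply(traces, function(tr)
      stats::approx(tr$time_s, tr$force, xout = t_ref, rule = 2)$y,
      numeric(length(t_ref)))
    rowMeans(matrix(m, nrow = length(t_ref)))
  }
  treated_f <- avg(treated)
  control_f <- avg(controls)
  if (any(control_f <= 0)) stop("control mean force is <= 0 somewhere")
  norm <- treated_f / control_f
  at0 <- stats::approx(t_ref, norm, xout = 0, rule = 2)$y
  if (at0 <= 0) stop("normalized force at t = 0 is <= 0")
  norm <- norm / at0
  vals <- stats::approx(t_ref, norm, xout = sample_times_min * 60, rule = 2)$y
  out <- data.frame(time_min = sample_times_min, normalized_force = vals)
  class(out) <- c("timecourse_result", "data.frame")
  out
}

#' Percent of force removed by treatment
#'
#' `100 * (before - after) / before`.
#'
#' @param before,after paired force values at matched condition.
#' @return percent scalar (vectorized).
#' @export
percent_force_removed <- function(before, after) {
  if (any(before <= 0)) stop("before-treatment force must be > 0")
  100 * (before - after) / before
}

#' Linear fit of force versus intact-titin fraction
#'
#' Ordinary least-squares fit per sarcomere length with the 95%
#' confidence band on the mean response, classified as weak
#' (R^2 < 0.5) or strong (R^2 >= 0.5).
#'
#' @param force numeric response values.
#' @param fraction intact-titin fraction covariate (same length).
#' @param sl_um sarcomere length tag carried through to the result.
#' @return a `correlation_fit`: list `sl_um, slope, intercept,
#'   r_squared, ci95_band` (data.frame `fraction, fit, lwr, upr`),
#'   `strength_class`.
#' @export
titin_force_correlation <- function(force, fraction, sl_um = NA_real_) {
  if (length(force) < 3) stop("need at least 3 points")
  stopifnot(length(force) == length(fraction))
  fit <- stats::lm(force ~ fraction)
  r2 <- summary(fit)$r.squared
  grid <- data.frame(fraction = seq(min(fraction), max(fraction),
                                    length.out = 25))
  band <- stats::predict(fit, grid, interval = "confidence", level = 0.95)
  structure(list(
    sl_um = sl_um,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    ci95_band = cbind(grid, as.data.frame(band)),
    strength_class = if (r2 < 0.5) "weak" else "strong"
  ), class = "correlation_fit")
}

#' Active force drop between paired contractions
#'
#' Steady-state force of each ~120 s activation is the mean over the
#' final `plateau_window_s`; the trace must have plateaued (terminal
#' slope below `slope_tol` per second, relative to the steady state).
#' The percent drop of the second (post-treatment) contraction is
#' reported, optionally corrected by the mean drop of an untreated
#' control pair.
#'
#' @param first,second `force_trace`s of the two contractions.
#' @param control_drop_percent optional mean drop of untreated controls.
#' @param plateau_window_s steady-state averaging window, s.
#' @param slope_tol maximum allowed relative terminal slope, per s.
#' @return an `activation_result`: list `steady_state_first,
#'   steady_state_second, percent_drop, control_corrected_drop`.
#' @export
active_force_drop <- function(first, second, control_drop_percent = NULL,
                              plateau_window_s = 10, slope_tol = 0.002) {
  ss <- function(tr) {
    t <- tr$time_s; f <- tr$force
    if (max(t) - min(t) < 60) stop("trace shorter than a 60 s activation")
    sel <- t >= max(t) - plateau_window_s
    s <- mean(f[sel])
    slope <- stats::coef(stats::lm(f[sel] ~ t[sel]))[2]
    if (abs(slope) > slope_tol * abs(s))
      stop("no plateau detected: terminal slope above tolerance")
    s
  }
  s1 <- ss(first); s2 <- ss(second)
  if (s1 <= 0 || s2 <= 0) stop("steady-state forces must be > 0")
  drop <- 100 * (1 - s2 / s1)
  structure(list(
    steady_state_first = s1, steady_state_second = s2,
    percent_drop = drop,
    control_corrected_drop = if (is.null(control_drop_percent)) NA_real_
                             else drop - control_drop_percent
  ), class = "activation_result")
}
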