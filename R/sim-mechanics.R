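# Ramp-hold force trace generator: exact piecewise-analytic integration
# of a generalized Maxwell model under piecewise-linear length input.
#
# Each Maxwell arm (k, tau) under constant lengthening velocity v obeys
#   dF/dt = k v - F / tau
# with solution F(t) = F0 e^(-dt/tau) + k v tau (1 - e^(-dt/tau));
# holds are the v = 0 case. The parallel spring contributes
# k_elastic * (SL - slack).

#' Generate a ramp-hold passive force trace
#'
#' Simulates the stepwise stretch-hold protocol used for passive fiber
#' mechanics (default emulates six 0.2 um SL steps at 0.2 um/s from a
#' 2.2 um slack length with 10 s isometric holds) and the exact
#' generalized-Maxwell force response, sampled at 1000 Hz.
#'
#' @param model a [viscoelastic_model()].
#' @param protocol data.frame with columns `delta_sl_um` (signed step),
#'   `speed_um_s` (> 0) and `hold_s` (>= 0); steps are applied in order
#'   starting from the model slack length.
#' @param fs sampling rate, Hz (default 1000).
#' @param seed integer RNG seed (noise only).
#' @return a `force_trace`: data.frame `time_s, sl_um, force` with
#'   attributes `units = "normalized"` and `meta`.
#' @export
gen_ramp_hold_trace <- function(model, protocol = default_ramp_protocol(),
                                fs = 1000, seed = 1) {
  stopifnot(inherits(model, "viscoelastic_model"))
  if (nrow(protocol) == 0) stop("protocol must be non-empty")
  if (any(protocol$speed_um_s <= 0)) stop("ramp speed must be > 0")
  if (any(protocol$hold_s < 0)) stop("hold duration must be >= 0")
  set.seed(seed)
  dt <- 1 / fs

  arms <- model$maxwell_arms
  n_arm <- nrow(arms)
  sl <- model$slack_sl_um
  arm_state <- rep(0, n_arm)

  seg_time <- list(); seg_sl <- list(); seg_visc <- list()
  t0 <- 0
  add_segment <- function(duration, v) {
    n <- max(1L, round(duration * fs))
    tt <- t0 + seq_len(n) * dt
    sls <- sl + v * (tt - t0)
    visc <- matrix(0, n, 1)
    if (n_arm > 0) {
      visc <- rep(0, n)
      for (a in seq_len(n_arm)) {
        k <- arms$k[a]; tau <- arms$tau[a]
        e <- exp(-(tt - t0) / tau)
        fa <- arm_state[a] * e + k * v * tau * (1 - e)
        visc <- visc + fa
        arm_state[a] <<- fa[n]
      }
    } else visc <- rep(0, n)
    seg_time[[length(seg_time) + 1L]] <<- tt
    seg_sl[[length(seg_sl) + 1L]] <<- sls
    seg_visc[[length(seg_visc) + 1L]] <<- visc
    t0 <<- tt[n]
    sl <<- sls[n]
  }

  for (i in seq_len(nrow(protocol))) {
    d <- protocol$delta_sl_um[i]
    v <- sign(d) * protocol$speed_um_s[i]
    if (d != 0) add_segment(abs(d) / protocol$speed_um_s[i], v)
    if (protocol$hold_s[i] > 0) add_segment(protocol$hold_s[i], 0)
  }

  time_s <- c(0, unlist(seg_time))
  sl_um <- c(model$slack_sl_um, unlist(seg_sl))
  visc <- c(0, unlist(seg_visc))
  scale <- model$baseline_fraction +
    (1 - model$baseline_fraction) * model$titin_fraction
  force <- scale * (model$k_elastic * (sl_um - model$slack_sl_um) + visc)
  if (model$noise_sd > 0)
    force <- force + stats::rnorm(length(force), 0, model$noise_sd)

  out <- data.frame(time_s = time_s, sl_um = sl_um, force = force)
  attr(out, "units") <- "normalized"
  attr(out, "meta") <- list(model = model, protocol = protocol, fs = fs)
  class(out) <- c("force_trace", "data.frame")
  out
}

#' Default six-step stretch-hold protocol
#'
#' Six incremental 0.2 um SL stretch-hold steps at 0.2 um/s with 10 s
#' isometric holds (2.2 to 3.4 um SL).
#'
#' @param n_steps number of steps.
#' @param delta_sl_um step size, um.
#' @param speed_um_s ramp speed, um/s.
#' @param hold_s hold duration, s.
#' @return protocol data.frame for [gen_ramp_hold_trace()].
#' @export
default_ramp_protocol <- function(n_steps = 6, delta_sl_um = 0.2,
                                  speed_um_s = 0.2, hold_s = 10) {
  data.frame(delta_sl_um = rep(delta_sl_um, n_steps),
             speed_um_s = rep(speed_um_s, n_steps),
             hold_s = rep(hold_s, n_steps))
}

#' Generate a long-hold trace for protease timecourse experiments
#'
#' Emulates the hold-at-length protocol in which fibers are stretched to
#' a long SL, allowed to stress-relax, and then (optionally) the titin
#' component decays exponentially after protease addition at `t = 0`.
#' Both treated and control traces share the stress-relaxation term so
#' that time-matched control division isolates the cleavage effect.
#'
#' @param titin_share fraction of the starting force carried by
#'   cleavable titin (in `[0, 1]`).
#' @param cleave_tau_min exponential time constant of titin-force loss
#'   after protease addition, minutes; `Inf` for an untreated control.
#' @param relax_tau_min time constant of ordinary stress relaxation
#'   (shared by treated and control), minutes.
#' @param relax_share fraction of the starting force that relaxes away.
#' @param duration_min trace duration after protease addition, minutes.
#' @param fs sampling rate, Hz.
#' @param sl_um hold sarcomere length recorded in the SL channel.
#' @param noise_sd additive force noise SD.
#' @param seed integer RNG seed.
#' @return a `force_trace` (time in s from protease addition).
#' @export
gen_hold_timecourse <- function(titin_share = 0.6744, cleave_tau_min = 4,
                                relax_tau_min = 30, relax_share = 0.15,
                                duration_min = 30, fs = 10, sl_um = 3.3,
                                noise_sd = 0, seed = 1) {
  if (titin_share < 0 || titin_share > 1) stop("titin_share must be in [0, 1]")
  set.seed(seed)
  t_min <- seq(0, duration_min, by = 1 / (fs * 60))
  relax <- (1 - relax_share) + relax_share * exp(-t_min / relax_tau_min)
  titin <- if (is.finite(cleave_tau_min))
    titin_share * exp(-t_min / cleave_tau_min) else rep(titin_share, length(t_min))
  force <- relax * (titin + (1 - titin_share))
  if (noise_sd > 0) force <- force + stats::rnorm(length(force), 0, noise_sd)
  out <- data.frame(time_s = t_min * 60, sl_um = rep(sl_um, length(t_min)),
                    force = force)
  attr(out, "units") <- "normalized"
  class(out) <- c("force_trace", "data.frame")
  out
}

#' Generate an isometric activation trace
#'
#' Force rises mono-exponentially to a steady-state plateau after
#' activation and stays there; used for active force-drop analysis.
#'
#' @param plateau steady-state force level.
#' @param rise_tau_s activation time constant, s.
#' @param duration_s trace length, s (~120 s activation).
#' @param sl_um sarcomere length recorded in the SL channel.
#' @param fs sampling rate, Hz.
#' @param noise_sd additive force noise SD.
#' @param seed integer RNG seed.
#' @return a `force_trace`.
#' @export
gen_activation_trace <- function(plateau = 1, rise_tau_s = 8, duration_s = 120,
                                 sl_um = 2.6, fs = 100, noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, duration_s, by = 1 / fs)
  force <- plateau * (1 - exp(-t / rise_tau_s))
  if (noise_sd > 0) force <- force + stats::rnorm(length(force), 0, noise_sd)
  out <- data.frame(time_s = t, sl_um = rep(sl_um, length(t)), force = force)
  attr(out, "units") <- "normalized"
  class(out) <- c("force_trace", "data.frame")
  out
}
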