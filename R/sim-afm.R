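# Synthetic AFM spherical-indentation curves (Hertz contact model).

# Hertz prefactor in nN/nm^(3/2): F = c * delta^(3/2),
# c = (4/3) (E / (1 - nu^2)) sqrt(R); 1 kPa = 1e-6 nN/nm^2.
hertz_prefactor <- function(E_kpa, nu, R_um) {
  (4 / 3) * (E_kpa * 1e-6 / (1 - nu^2)) * sqrt(R_um * 1000)
}

#' Generate a synthetic force-indentation curve
#'
#' Piezo positions advance in fixed steps; force is a flat noisy
#' baseline before the contact offset and follows the Hertz sphere model
#' past it, truncated at the trigger force.
#'
#' @param spec a [hertz_curve_spec()].
#' @param dz_nm piezo step, nm.
#' @param pre_contact_nm length of the pre-contact baseline, nm.
#' @param z_max_nm optional hard end of the position range, nm; an error
#'   is raised if the trigger force is not reached within it.
#' @param seed integer RNG seed (noise only).
#' @return an `indentation_curve`: data.frame `position_nm, force_nn`
#'   with attributes `probe` (list `R_um`, `k_c`) and `truth` (the spec).
#' @export
gen_indentation_curve <- function(spec, dz_nm = 2, pre_contact_nm = NULL,
                                  z_max_nm = NULL, seed = 1) {
  stopifnot(inherits(spec, "hertz_curve_spec"))
  set.seed(seed)
  cpre <- hertz_prefactor(spec$E_kpa, spec$nu, spec$R_um)
  delta_max <- (spec$max_force_nn / cpre)^(2 / 3)
  if (is.null(pre_contact_nm)) pre_contact_nm <- spec$contact_offset_nm
  z_end <- spec$contact_offset_nm + delta_max
  if (!is.null(z_max_nm)) {
    if (z_max_nm < z_end)
      stop("trigger force unreachable within the position range")
  }
  z <- seq(spec$contact_offset_nm - pre_contact_nm, z_end + dz_nm, by = dz_nm)
  delta <- pmax(0, z - spec$contact_offset_nm)
  force <- cpre * delta^1.5
  if (spec$noise_sd_nn > 0)
    force <- force + stats::rnorm(length(force), 0, spec$noise_sd_nn)
  # truncate at the trigger: keep through the first sample at/above it
  ideal <- cpre * delta^1.5
  first_at <- which(ideal >= spec$max_force_nn)
  keep <- seq_len(if (length(first_at)) first_at[1] else length(z))
  out <- data.frame(position_nm = z[keep], force_nn = force[keep])
  attr(out, "probe") <- list(R_um = spec$R_um, k_c = NA_real_)
  attr(out, "truth") <- spec
  class(out) <- c("indentation_curve", "data.frame")
  out
}
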