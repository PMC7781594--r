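# Order-of-magnitude force balance between M-bridge loads and
# titin-based thick-filament centering forces.

#' Balance parameters for the thick-filament centering estimate
#'
#' Defaults restate the Discussion-level constants of the psoas
#' half-sarcomere: six titins per half-thick filament, ~500 parallel
#' thick filaments per um^2, M-band structures extensible up to ~70 nm
#' at low force, ~12 pN of titin force per molecule at a 35 nm length
#' change (2.65 um SL), and an upper opposing load of 120 pN.
#'
#' @param n_titins_per_half_filament count.
#' @param filament_density_per_um2 thick filaments per um^2.
#' @param mband_max_extension_nm maximal low-force M-band extension, nm.
#' @param per_molecule_force_pn per-titin force at the reference
#'   displacement, pN.
#' @param ref_displacement_nm reference displacement of
#'   `per_molecule_force_pn`, nm.
#' @param target_load_pn opposing M-bridge load, pN.
#' @param p0_fraction optional fraction of maximal force for expressing
#'   loads (in `(0, 1]`).
#' @return object of class `balance_params`.
#' @export
balance_params <- function(n_titins_per_half_filament = 6,
                           filament_density_per_um2 = 500,
                           mband_max_extension_nm = 70,
                           per_molecule_force_pn = 12,
                           ref_displacement_nm = 35,
                           target_load_pn = 120,
                           p0_fraction = NULL) {
  vals <- c(n_titins_per_half_filament, filament_density_per_um2,
            mband_max_extension_nm, per_molecule_force_pn,
            ref_displacement_nm, target_load_pn)
  if (any(vals <= 0)) stop("all counts, lengths and forces must be > 0")
  if (!is.null(p0_fraction) && (p0_fraction <= 0 || p0_fraction > 1))
    stop("p0_fraction must be in (0, 1]")
  structure(as.list(environment()), class = "balance_params")
}

#' Titin length change for a thick-filament displacement
#'
#' A thick filament displaced axially by `d` lengthens the titins on one
#' side by `d` and shortens those on the other by `d`; the allowed range
#' follows the half-extension convention of the M-band
#' (`0 <= d <= mband_max_extension_nm / 2`).
#'
#' @param displacement_nm axial displacement, nm.
#' @param mband_max_extension_nm maximal M-band extension, nm.
#' @return list `lengthening_nm` (+d), `shortening_nm` (-d).
#' @export
titin_length_change <- function(displacement_nm, mband_max_extension_nm = 70) {
  if (displacement_nm < 0 || displacement_nm > mband_max_extension_nm / 2)
    stop("displacement must be in [0, mband_max_extension_nm / 2]")
  list(lengthening_nm = displacement_nm, shortening_nm = -displacement_nm)
}

#' Titin-based thick-filament centering force
#'
#' Linear per-molecule stiffness around the operating point: the force
#' change per titin is `F_ref * d / d_ref`. With one-sided accounting
#' the net centering force per filament is `n * dF` (the lengthening
#' side only); with differential accounting both sides contribute,
#' `2 n * dF`. The stiffness multiplier is the factor by which
#' per-molecule stiffness must rise to meet `target_load_pn`.
#'
#' @param params a [balance_params()].
#' @param displacement_nm axial thick-filament displacement, nm.
#' @param convention `"one-sided"` or `"differential"` accounting.
#' @return a `balance_result`: list `displacement_nm,
#'   delta_titin_length_nm, per_molecule_force_pn, centering_force_pn,
#'   stiffness_multiplier_required, convention`.
#' @export
centering_force <- function(params = balance_params(), displacement_nm,
                            convention = c("one-sided", "differential")) {
  convention <- match.arg(convention)
  stopifnot(inherits(params, "balance_params"))
  if (params$ref_displacement_nm == 0) stop("reference displacement is 0")
  if (displacement_nm < 0) stop("displacement must be >= 0")
  dF <- params$per_molecule_force_pn *
    displacement_nm / params$ref_displacement_nm
  n <- params$n_titins_per_half_filament
  net <- if (convention == "one-sided") n * dF else 2 * n * dF
  if (net == 0)
    stop("zero centering force at zero displacement: multiplier undefined")
  structure(list(
    displacement_nm = displacement_nm,
    delta_titin_length_nm = displacement_nm,
    per_molecule_force_pn = dF,
    centering_force_pn = net,
    stiffness_multiplier_required = params$target_load_pn / net,
    convention = convention
  ), class = "balance_result")
}
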