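# Physical constants, package-wide unit system: nm, ns, kJ/mol, e, V.

#' Boltzmann constant in kJ/mol/K
#' @keywords internal
.kB <- 0.0083144621

#' kJ/mol per (elementary charge x volt); Faraday constant / 1000
#' @keywords internal
.eV_kJmol <- 96.485332

#' Elementary charge in coulomb
#' @keywords internal
.e_C <- 1.602176634e-19

#' Standard-state volume per molecule at 1 mol/L, in nm^3
#' @keywords internal
.std_volume_nm3 <- 1.6606

#' Thermal energy
#'
#' Thermal energy kT in kJ/mol at a given temperature.
#'
#' @param temperature temperature in K.
#' @return kT in kJ/mol (2.494 at 300 K).
#' @examples
#' thermal_energy(300)
#' @export
thermal_energy <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB * temperature
}
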