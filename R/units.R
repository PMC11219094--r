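#' Unit conventions and conversion helpers
#'
#' All energies inside the package are in reduced units: multiples of kT at
#' the reference temperature `t0` (300 K by default). Distances are in nm and
#' charges in elementary charge units (e). Reports convert to kcal/mol with
#' [kt_to_kcal()].
#'
#' @name alchemforge-units
NULL

# Boltzmann constant, kcal/(mol K)
.kB_kcal <- 0.0019872041

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return kT in kcal/mol.
#' @export
#' @examples
#' kt_kcal(300)
kt_kcal <- function(temperature = 300) {
  stopifnot(temperature > 0)
  .kB_kcal * temperature
}

#' Convert reduced energies (units of kT) to kcal/mol
#'
#' @param x Energy in units of kT at `temperature`.
#' @param temperature Reference temperature in Kelvin.
#' @return Energy in kcal/mol.
#' @export
kt_to_kcal <- function(x, temperature = 300) {
  x * kt_kcal(temperature)
}

#' Convert kcal/mol to reduced energy units
#'
#' @inheritParams kt_to_kcal
#' @param x Energy in kcal/mol.
#' @export
kcal_to_kt <- function(x, temperature = 300) {
  x / kt_kcal(temperature)
}

#' Coulomb constant in reduced units
#'
#' The Coulomb prefactor C such that C q_i q_j / r is an energy in kT at
#' `temperature`, with charges in e and r in nm.
#'
#' @param temperature Reference temperature in Kelvin.
#' @return Coulomb constant in kT nm / e^2.
#' @export
coulomb_constant_kt <- function(temperature = 300) {
  # 332.0637 kcal A / (mol e^2) = 33.20637 kcal nm / (mol e^2)
  33.20637 / kt_kcal(temperature)
}
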