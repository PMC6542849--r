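# Physical constants (SI, CODATA 2018)

#' Physical constants used throughout the package
#'
#' A named list of physical constants in SI units: elementary charge `e` (C),
#' Boltzmann constant `kB` (J/K), Avogadro constant `N_A` (1/mol), Faraday
#' constant `F` (C/mol), and vacuum permittivity `eps0` (F/m).
#'
#' @format Named list of length 5.
#' @export
pn_constants <- list(
  e    = 1.602176634e-19,
  kB   = 1.380649e-23,
  N_A  = 6.02214076e23,
  F    = 96485.33212,
  eps0 = 8.8541878128e-12
)

# thermal voltage kB*T/e in volts
thermal_voltage <- function(T) pn_constants$kB * T / pn_constants$e
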