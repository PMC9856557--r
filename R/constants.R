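#' Physical constants
#'
#' Fixed CODATA values used throughout the DLVO and acoustic models.
#' These are physical constants, not tunable parameters, and are therefore
#' not exposed through the configuration system.
#'
#' @return A list with components
#'   \item{e}{elementary charge (C)}
#'   \item{N_A}{Avogadro constant (1/mol)}
#'   \item{k_B}{Boltzmann constant (J/K)}
#'   \item{eps0}{vacuum permittivity (C^2/(N m^2))}
#' @examples
#' physical_constants()$k_B
#' @export
physical_constants <- function() {
  list(
    e    = 1.602176634e-19,
    N_A  = 6.02214076e23,
    k_B  = 1.380649e-23,
    eps0 = 8.8541878128e-12
  )
}

# Celsius <-> Kelvin helpers used across modules
celsius_to_kelvin <- function(tC) tC + 273.15
kelvin_to_celsius <- function(tK) tK - 273.15
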