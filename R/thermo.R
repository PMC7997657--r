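#' Thermodynamic state
#'
#' Bundles the temperature and Boltzmann constant used throughout the
#' free-energy computations. `kT` and `beta = 1/kT` are derived.
#'
#' @param temperature Heat-bath temperature in kelvin. Default 310 K.
#' @param boltzmann_constant Boltzmann constant in kcal mol^-1 K^-1.
#'   Default 0.0019872041.
#' @return An object of class `"thermo"` with fields `temperature`,
#'   `boltzmann_constant`, `kT` (kcal mol^-1) and `beta` (mol kcal^-1).
#' @examples
#' th <- thermo()
#' th$kT # ~0.616 kcal/mol at 310 K
#' @export
thermo <- function(temperature = 310, boltzmann_constant = 0.0019872041) {
  stop_if_not_scalar(temperature, "temperature", positive = TRUE)
  stop_if_not_scalar(boltzmann_constant, "boltzmann_constant", positive = TRUE)
  kT <- boltzmann_constant * temperature
  structure(
    list(
      temperature = temperature,
      boltzmann_constant = boltzmann_constant,
      kT = kT,
      beta = 1 / kT
    ),
    class = "thermo"
  )
}

#' @export
print.thermo <- function(x, ...) {
  cat(sprintf(
    "Thermodynamic state: T = %g K, k_B = %g kcal/mol/K, kT = %.6g kcal/mol\n",
    x$temperature, x$boltzmann_constant, x$kT
  ))
  invisible(x)
}
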