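#' Thermal energy in pN nm
#'
#' Boltzmann constant times absolute temperature, in the piconewton-nanometre
#' units natural to optical tweezers (kB = 0.0138065 pN nm / K). At the
#' instrument temperature of 23 degrees C this is 4.089 pN nm, the value used
#' throughout the package whenever a force times a length is expressed in kBT.
#'
#' @param temperature_C temperature in degrees Celsius. Default 23.
#' @return thermal energy kB*T in pN nm.
#' @examples
#' boltzmann_energy(23)   # 4.089 pN nm
#' @export
boltzmann_energy <- function(temperature_C = 23) {
  if (!is.numeric(temperature_C) || any(!is.finite(temperature_C)))
    stop("`temperature_C` must be finite and numeric")
  if (any(temperature_C <= -273.15))
    stop("nonphysical temperature: at or below absolute zero")
  0.0138065 * (temperature_C + 273.15)
}

#' Unit constants for B-to-S transition analysis
#'
#' @param temperature_C temperature in degrees Celsius used for the thermal
#'   energy. Default 23.
#' @return a list with `kbt` (pN nm), `x_BS` (per-bp elongation of the
#'   B-to-S transition, 0.23 nm/bp, known from polymeric DNA overstretching),
#'   `kcal_per_kBT` (0.59 kcal/mol per kBT) and `temperature_C`.
#' @examples
#' bs_constants()$kbt
#' @export
bs_constants <- function(temperature_C = 23) {
  list(
    kbt          = boltzmann_energy(temperature_C),
    x_BS         = 0.23,
    kcal_per_kBT = 0.59,
    temperature_C = temperature_C
  )
}
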