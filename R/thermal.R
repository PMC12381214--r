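#' Thermal context for force-spectroscopy calculations
#'
#' Bundles the temperature and Boltzmann constant used throughout the
#' package. All mechanical energies are carried in pN.nm, so
#' `kB = 0.013807` pN.nm/K and `kB * T` is about 4.12 pN.nm at room
#' temperature. The inverse thermal energy `beta = 1/(kB*T)` multiplies
#' every force-distance product in the kinetic models.
#'
#' @param temperature Absolute temperature in K. Default 298.15.
#' @param boltzmann_kB Boltzmann constant in pN.nm/K. Default 0.013807.
#' @return An object of class `thermal_context` with elements
#'   `temperature`, `kB`, `kBT` (pN.nm) and `beta` (1/(pN.nm)).
#' @examples
#' ctx <- thermal_context()
#' ctx$kBT
#' @export
thermal_context <- function(temperature = 298.15, boltzmann_kB = 0.013807) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(boltzmann_kB), length(boltzmann_kB) == 1L)
  if (temperature <= 0) stop("temperature must be > 0 K")
  if (boltzmann_kB <= 0) stop("boltzmann_kB must be > 0")
  kBT <- boltzmann_kB * temperature
  structure(
    list(temperature = temperature, kB = boltzmann_kB,
         kBT = kBT, beta = 1 / kBT),
    class = "thermal_context"
  )
}

#' @export
print.thermal_context <- function(x, ...) {
  cat(sprintf("<thermal_context> T = %.2f K, kBT = %.4f pN.nm\n",
              x$temperature, x$kBT))
  invisible(x)
}
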