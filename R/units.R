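# Package-wide unit conventions: length nm, force pN, time s, energy pN.nm.
# Spring constants are accepted in N/m at user-facing boundaries and converted
# internally to pN/nm (1 N/m = 1e12 pN / 1e9 nm = 1000 pN/nm).

#' Boltzmann constant in pN nm / K
#'
#' @format Length-one numeric, 0.01380649 pN nm / K (exact SI value rescaled).
#' @keywords internal
kB_pN_nm <- 1.380649e-2

#' Thermal energy k_B T
#'
#' Thermal energy in piconewton-nanometres at a given absolute temperature.
#' At the package default of 298 K this is 4.114 pN nm.
#'
#' @param temperature Absolute temperature in kelvin.
#' @return Thermal energy in pN nm.
#' @examples
#' thermal_energy()      # 4.114 pN nm
#' thermal_energy(310)
#' @export
thermal_energy <- function(temperature = 298) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be positive and finite (kelvin)")
  }
  kB_pN_nm * temperature
}

#' Convert a spring constant between N/m and pN/nm
#'
#' AFM cantilever spring constants are conventionally quoted in N/m;
#' internally all stiffnesses are carried in pN/nm (1 N/m = 1000 pN/nm).
#'
#' @param k Spring constant value(s).
#' @param from,to Units, either `"N/m"` or `"pN/nm"`.
#' @return Spring constant in the `to` unit.
#' @examples
#' convert_spring_constant(0.15, "N/m", "pN/nm")  # 150
#' @export
convert_spring_constant <- function(k, from = c("N/m", "pN/nm"),
                                    to = c("pN/nm", "N/m")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(k)
  if (from == "N/m") k * 1000 else k / 1000
}
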