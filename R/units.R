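# Unit conversions between mole fraction (ppb) and amount concentration
# (nmol m^-3).  All internal computation uses seconds, ppb and nmol.

# molar gas constant, J K^-1 mol^-1 (CODATA 2018)
.R_GAS <- 8.314462618

#' Convert a mole fraction in ppb to an amount concentration
#'
#' Uses the ideal gas law: a trace gas at mole fraction `x` ppb in air at
#' temperature `temperature` and pressure `pressure` has amount
#' concentration `x * pressure / (R * temperature)` nmol m^-3.  At the
#' default conditions (293.15 K, 101325 Pa) 1 ppb corresponds to about
#' 41.57 nmol m^-3.
#'
#' @param x mole fraction, ppb. May be a vector.
#' @param temperature air temperature, K.
#' @param pressure air pressure, Pa.
#' @return amount concentration, nmol m^-3.
#' @seealso [amount_concentration_to_ppb()] for the inverse.
#' @examples
#' ppb_to_amount_concentration(325)  # ambient N2O, ~1.35e4 nmol m^-3
#' @export
ppb_to_amount_concentration <- function(x, temperature = 293.15, pressure = 101325) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric (ppb)")
  if (!isTRUE(temperature > 0)) stop("'temperature' must be > 0 K")
  if (!isTRUE(pressure > 0)) stop("'pressure' must be > 0 Pa")
  x * pressure / (.R_GAS * temperature)
}

#' Convert an amount concentration to a mole fraction in ppb
#'
#' Inverse of [ppb_to_amount_concentration()].
#'
#' @param x amount concentration, nmol m^-3.
#' @inheritParams ppb_to_amount_concentration
#' @return mole fraction, ppb.
#' @export
amount_concentration_to_ppb <- function(x, temperature = 293.15, pressure = 101325) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric (nmol m^-3)")
  if (!isTRUE(temperature > 0)) stop("'temperature' must be > 0 K")
  if (!isTRUE(pressure > 0)) stop("'pressure' must be > 0 Pa")
  x * .R_GAS * temperature / pressure
}

# nmol m^-3 per ppb for a chamber system; the factor that turns a
# concentration slope (ppb/s) times chamber height (m) into a flux
# (nmol s^-1 m^-2)
.conv_factor <- function(system) {
  ppb_to_amount_concentration(1, system$temperature, system$pressure)
}
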