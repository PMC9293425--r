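#' Physical and model constants
#'
#' Bundle of physical constants and model reference temperatures used
#' throughout the package. All internal computation is in SI units
#' (J mol^-1, J mol^-1 K^-1, K, Pa); user-facing functions accept degrees
#' Celsius and the reporting layer converts enthalpy/heat-capacity terms to
#' kJ for presentation.
#'
#' @param R_gas Universal gas constant, J mol^-1 K^-1.
#' @param k_B Boltzmann constant, J K^-1.
#' @param h_planck Planck constant, J s.
#' @param T0 Reference temperature for the transition-state parameters, K.
#'   298.15 K (25 degC) keeps the Celsius/Kelvin conversion exact.
#' @param P_atm Atmospheric pressure used for headspace gas calculations, Pa.
#' @param lt_T0_offset Lloyd & Taylor zero-rate temperature, K. With the
#'   canonical 227.13 K the model's basal rate parameter is the rate at
#'   exactly 10 degC.
#' @param lt_ref_span Lloyd & Taylor reference span, K (283.15 - 227.13).
#'
#' @return An object of class `thermo_constants` (a named list).
#' @examples
#' cc <- thermo_constants()
#' cc$R_gas
#' @export
thermo_constants <- function(R_gas = 8.314,
                             k_B = 1.380649e-23,
                             h_planck = 6.62607015e-34,
                             T0 = 298.15,
                             P_atm = 101325,
                             lt_T0_offset = 227.13,
                             lt_ref_span = 56.02) {
  vals <- c(R_gas = R_gas, k_B = k_B, h_planck = h_planck, T0 = T0,
            P_atm = P_atm, lt_T0_offset = lt_T0_offset,
            lt_ref_span = lt_ref_span)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all thermodynamic constants must be finite and strictly positive",
         call. = FALSE)
  }
  if (T0 <= lt_T0_offset) {
    stop("T0 must exceed the Lloyd & Taylor zero-rate temperature",
         call. = FALSE)
  }
  structure(as.list(vals), class = "thermo_constants")
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat("Thermodynamic constants:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Convert between Celsius and Kelvin
#'
#' The 273.15 offset is exact by definition. The package's data layer
#' (CSV columns, curves, fits) works in degC; the thermodynamic model
#' functions take Kelvin.
#'
#' @param x Temperature(s).
#' @return Converted temperature(s).
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15
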