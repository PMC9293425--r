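#' MMRT parameter set
#'
#' The three fitted parameters of macromolecular rate theory (MMRT):
#' activation enthalpy and entropy at the reference temperature, and the
#' activation heat-capacity change. MMRT extends transition-state theory
#' with a non-zero activation heat capacity \eqn{\Delta C_P^\ddagger},
#' which makes the Arrhenius plot curved and gives the rate a temperature
#' optimum. For enzyme-driven processes \eqn{\Delta C_P^\ddagger} is
#' negative.
#'
#' @param dH0 Activation enthalpy at the reference temperature, J mol^-1.
#' @param dCp Activation heat-capacity change, J mol^-1 K^-1.
#' @param dS0 Activation entropy at the reference temperature,
#'   J mol^-1 K^-1.
#' @return An object of class `mmrt_params`.
#' @examples
#' mmrt_params(dH0 = 73400, dCp = -1400, dS0 = 27.7)
#' @export
mmrt_params <- function(dH0, dCp, dS0) {
  if (!all(is.finite(c(dH0, dCp, dS0)))) {
    stop("MMRT parameters must be finite", call. = FALSE)
  }
  structure(list(dH0 = dH0, dCp = dCp, dS0 = dS0), class = "mmrt_params")
}

#' @export
print.mmrt_params <- function(x, ...) {
  cat(sprintf(
    "MMRT parameters: dH0 = %.4g J/mol, dCp = %.4g J/mol/K, dS0 = %.4g J/mol/K\n",
    x$dH0, x$dCp, x$dS0))
  invisible(x)
}

#' Lloyd & Taylor parameter set
#'
#' Parameters of the Lloyd & Taylor empirical respiration model: the log
#' basal rate at 10 degC and the temperature-sensitivity parameter E0 (K).
#'
#' @param lnR10 Natural log of the basal rate at 10 degC.
#' @param E0 Temperature-sensitivity parameter, K. Positive for
#'   physically increasing curves.
#' @return An object of class `lt_params`.
#' @export
lt_params <- function(lnR10, E0) {
  if (!all(is.finite(c(lnR10, E0)))) {
    stop("Lloyd & Taylor parameters must be finite", call. = FALSE)
  }
  structure(list(lnR10 = lnR10, E0 = E0), class = "lt_params")
}

#' @export
print.lt_params <- function(x, ...) {
  cat(sprintf("Lloyd & Taylor parameters: lnR10 = %.4g (R10 = %.4g), E0 = %.4g K\n",
              x$lnR10, exp(x$lnR10), x$E0))
  invisible(x)
}

#' MMRT log rate
#'
#' Log respiration rate under macromolecular rate theory:
#' \deqn{\ln R = \ln\frac{k_B T}{h}
#'   - \frac{\Delta H_{T_0}^\ddagger + \Delta C_P^\ddagger (T - T_0)}{R T}
#'   + \frac{\Delta S_{T_0}^\ddagger + \Delta C_P^\ddagger \ln(T/T_0)}{R}}
#' The expression is exactly linear in (dH0, dCp, dS0) at fixed
#' temperature, which is what makes the model fit a linear least-squares
#' problem on the log scale.
#'
#' @param params An [mmrt_params()] object.
#' @param temp_K Temperature(s), K. Must be strictly positive.
#' @param constants A [thermo_constants()] object.
#' @return Log rate (same length as `temp_K`).
#' @examples
#' p <- mmrt_params(73400, -1400, 27.72)
#' exp(mmrt_log_rate(p, 298.15))  # rate at 25 degC
#' @export
mmrt_log_rate <- function(params, temp_K, constants = thermo_constants()) {
  stopifnot(inherits(params, "mmrt_params"))
  if (any(!is.finite(temp_K)) || any(temp_K <= 0)) {
    stop("temperature must be finite and positive (Kelvin)", call. = FALSE)
  }
  R <- constants$R_gas
  T0 <- constants$T0
  log(constants$k_B * temp_K / constants$h_planck) -
    (params$dH0 + params$dCp * (temp_K - T0)) / (R * temp_K) +
    (params$dS0 + params$dCp * log(temp_K / T0)) / R
}

#' Temperature optimum of the MMRT rate curve
#'
#' Closed form for the temperature at which the MMRT rate is maximal:
#' \deqn{T_{opt} = \frac{\Delta H_{T_0}^\ddagger - \Delta C_P^\ddagger T_0}
#'   {-\Delta C_P^\ddagger - R}}
#' Defined only when \eqn{\Delta C_P^\ddagger < -R} (the curve must bend
#' over); otherwise the rate has no interior maximum.
#'
#' @inheritParams mmrt_log_rate
#' @return Temperature optimum, K.
#' @export
t_opt <- function(params, constants = thermo_constants()) {
  stopifnot(inherits(params, "mmrt_params"))
  R <- constants$R_gas
  if (params$dCp >= -R) {
    stop("no temperature optimum: dCp must be < -R_gas", call. = FALSE)
  }
  (params$dH0 - params$dCp * constants$T0) / (-params$dCp - R)
}

#' Inflection temperature of the MMRT rate curve
#'
#' Temperature at which the absolute sensitivity dR/dT is greatest:
#' \deqn{T_{inf} = \frac{\Delta H_{T_0}^\ddagger - \Delta C_P^\ddagger T_0}
#'   {-\Delta C_P^\ddagger + \sqrt{-\Delta C_P^\ddagger R}}}
#' Requires \eqn{\Delta C_P^\ddagger < 0}. Lies below [t_opt()] whenever
#' the optimum exists.
#'
#' @inheritParams mmrt_log_rate
#' @return Inflection temperature, K.
#' @export
t_inf <- function(params, constants = thermo_constants()) {
  stopifnot(inherits(params, "mmrt_params"))
  R <- constants$R_gas
  if (params$dCp >= 0) {
    stop("inflection temperature requires dCp < 0", call. = FALSE)
  }
  (params$dH0 - params$dCp * constants$T0) /
    (-params$dCp + sqrt(-params$dCp * R))
}

#' Rate at the 25 degC reference temperature
#'
#' \deqn{R_{25} = \exp\left(\ln\frac{k_B T_0}{h} -
#'   \frac{\Delta G_{T_0}^\ddagger}{R T_0}\right)} with
#' \eqn{\Delta G_{T_0}^\ddagger = \Delta H_{T_0}^\ddagger - T_0
#' \Delta S_{T_0}^\ddagger}. Identically equal to
#' `exp(mmrt_log_rate(params, T0))`: at the reference temperature the
#' heat-capacity terms vanish.
#'
#' @inheritParams mmrt_log_rate
#' @return Rate at 25 degC (rate units of the fitted data).
#' @export
r25 <- function(params, constants = thermo_constants()) {
  stopifnot(inherits(params, "mmrt_params"))
  dG0 <- params$dH0 - constants$T0 * params$dS0
  exp(log(constants$k_B * constants$T0 / constants$h_planck) -
        dG0 / (constants$R_gas * constants$T0))
}

#' Activation Gibbs energy at the reference temperature
#'
#' @inheritParams mmrt_log_rate
#' @return \eqn{\Delta G_{T_0}^\ddagger} in J mol^-1.
#' @export
dG0 <- function(params, constants = thermo_constants()) {
  stopifnot(inherits(params, "mmrt_params"))
  params$dH0 - constants$T0 * params$dS0
}

#' Q10 from MMRT parameters (printed-form approximation)
#'
#' Relative temperature sensitivity expressed as the familiar Q10
#' (rate ratio over a 10 K interval) derived from the MMRT parameters:
#' \deqn{Q_{10} = \exp\frac{10\,[\Delta H^\ddagger(T) -
#'   5\,\Delta C_P^\ddagger]}{R T^2}, \qquad
#'   \Delta H^\ddagger(T) = \Delta H_{T_0}^\ddagger +
#'   \Delta C_P^\ddagger (T - T_0)}
#' This is a local (Taylor-type) approximation centred at T; the factor 5
#' carries units of K. The companion [q10_exact()] evaluates the exact
#' forward rate ratio and agrees closely over the biologically relevant
#' range.
#'
#' @inheritParams mmrt_log_rate
#' @return Dimensionless Q10 ratio (vectorised over `temp_K`).
#' @export
q10_mmrt <- function(params, temp_K, constants = thermo_constants()) {
  stopifnot(inherits(params, "mmrt_params"))
  if (any(temp_K <= 0)) stop("temperature must be positive (Kelvin)", call. = FALSE)
  dH_T <- params$dH0 + params$dCp * (temp_K - constants$T0)
  exp(10 * (dH_T - 5 * params$dCp) / (constants$R_gas * temp_K^2))
}

#' Exact Q10 as a forward rate ratio
#'
#' `exp(mmrt_log_rate(T + 10) - mmrt_log_rate(T))`, the unambiguous
#' definition of the 10 K rate ratio.
#'
#' @inheritParams mmrt_log_rate
#' @export
q10_exact <- function(params, temp_K, constants = thermo_constants()) {
  exp(mmrt_log_rate(params, temp_K + 10, constants) -
        mmrt_log_rate(params, temp_K, constants))
}

#' Lloyd & Taylor log rate
#'
#' \deqn{\ln R = \ln R_{10} + E_0\left(\frac{1}{56.02} -
#'   \frac{1}{T - 227.13}\right)}
#' With the canonical constants the bracket vanishes at T = 283.15 K, so
#' R10 is exactly the rate at 10 degC. Linear in (lnR10, E0) at fixed
#' temperature.
#'
#' @param params An [lt_params()] object.
#' @param temp_K Temperature(s), K; must exceed the zero-rate offset.
#' @param constants A [thermo_constants()] object.
#' @export
lt_log_rate <- function(params, temp_K, constants = thermo_constants()) {
  stopifnot(inherits(params, "lt_params"))
  if (any(!is.finite(temp_K)) || any(temp_K <= constants$lt_T0_offset)) {
    stop("temperature must exceed the Lloyd & Taylor zero-rate offset",
         call. = FALSE)
  }
  params$lnR10 + params$E0 *
    (1 / constants$lt_ref_span - 1 / (temp_K - constants$lt_T0_offset))
}

#' Q10 from the Lloyd & Taylor model
#'
#' \deqn{Q_{10} = \exp\frac{10 E_0}{(T - 227.13)^2}}
#' Greater than 1 for positive E0 and monotonically decreasing in
#' temperature.
#'
#' @param E0 Temperature-sensitivity parameter, K.
#' @param temp_K Temperature(s), K.
#' @param constants A [thermo_constants()] object.
#' @export
q10_lt <- function(E0, temp_K, constants = thermo_constants()) {
  if (any(!is.finite(temp_K)) || any(temp_K <= constants$lt_T0_offset)) {
    stop("temperature must exceed the Lloyd & Taylor zero-rate offset",
         call. = FALSE)
  }
  exp(10 * E0 / (temp_K - constants$lt_T0_offset)^2)
}

#' Relative temperature sensitivity of the MMRT rate
#'
#' Analytic derivative of the log rate with respect to temperature,
#' \eqn{d\ln R/dT = 1/T + [\Delta H_{T_0}^\ddagger +
#' \Delta C_P^\ddagger (T - T_0)]/(R T^2)}, i.e. the proportional change
#' in rate per K. Zero exactly at the temperature optimum. Unlike the
#' absolute sensitivity dR/dT it does not depend on the size of the
#' substrate pool, which is why it is the quantity that reflects the
#' physiology of the microbial community.
#'
#' @inheritParams mmrt_log_rate
#' @return Sensitivity in K^-1.
#' @export
relative_sensitivity <- function(params, temp_K,
                                 constants = thermo_constants()) {
  stopifnot(inherits(params, "mmrt_params"))
  if (any(temp_K <= 0)) stop("temperature must be positive (Kelvin)", call. = FALSE)
  1 / temp_K + (params$dH0 + params$dCp * (temp_K - constants$T0)) /
    (constants$R_gas * temp_K^2)
}

#' Recover MMRT parameters from thermal traits
#'
#' Algebraic inversion of the closed forms for the temperature optimum and
#' the 25 degC rate: given a target T_opt (K), heat-capacity change and
#' R25, return the unique MMRT parameter set with those traits. Used by
#' the synthetic-data generator to plant environment-linked traits whose
#' recovery the fitting pipeline can then be tested against.
#'
#' @param T_opt Target temperature optimum, K.
#' @param dCp Activation heat-capacity change, J mol^-1 K^-1; must be
#'   below `-R_gas`.
#' @param R25 Target rate at 25 degC; must be positive.
#' @param constants A [thermo_constants()] object.
#' @return An [mmrt_params()] object satisfying
#'   `t_opt(res) == T_opt` and `r25(res) == R25` (to floating point).
#' @examples
#' p <- invert_traits(T_opt = 352.7, dCp = -1400, R25 = 24.1)
#' t_opt(p)  # 352.7
#' r25(p)    # 24.1
#' @export
invert_traits <- function(T_opt, dCp, R25, constants = thermo_constants()) {
  R <- constants$R_gas
  T0 <- constants$T0
  if (!is.finite(T_opt) || T_opt <= 0) {
    stop("T_opt must be a positive temperature in K", call. = FALSE)
  }
  if (!is.finite(dCp) || dCp >= -R) {
    stop("dCp must be < -R_gas for a defined optimum", call. = FALSE)
  }
  if (!is.finite(R25) || R25 <= 0) stop("R25 must be positive", call. = FALSE)
  dH0 <- T_opt * (-dCp - R) + dCp * T0
  dG0 <- R * T0 * (log(constants$k_B * T0 / constants$h_planck) - log(R25))
  dS0 <- (dH0 - dG0) / T0
  mmrt_params(dH0 = dH0, dCp = dCp, dS0 = dS0)
}

#' Thermal traits of an MMRT parameter set
#'
#' Convenience wrapper returning the derived traits in reporting units
#' (degC for temperatures, kJ mol^-1 for the Gibbs energy).
#'
#' @inheritParams mmrt_log_rate
#' @return A one-row data frame with `t_opt_C`, `t_inf_C`, `r25`,
#'   `dG0_kJ`.
#' @export
thermal_traits <- function(params, constants = thermo_constants()) {
  data.frame(
    t_opt_C = kelvin_to_celsius(t_opt(params, constants)),
    t_inf_C = kelvin_to_celsius(t_inf(params, constants)),
    r25 = r25(params, constants),
    dG0_kJ = dG0(params, constants) / 1000
  )
}
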