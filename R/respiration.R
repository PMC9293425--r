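#' Soil mass used at a given target incubation temperature
#'
#' Incubations at low temperature need more soil to produce a measurable
#' headspace CO2 change in a similar time, so the protocol scales the soil
#' mass down with temperature: 4 g (dry-mass equivalent) below 20 degC,
#' 3 g for 20 up to 30 degC, 2 g for 30 up to 38 degC and 1 g at 38 degC
#' and above. Intervals are closed on the left (a 38 degC target gets
#' 1 g).
#'
#' @param target_T Target incubation temperature(s), degC.
#' @return Soil dry mass in g (vectorised).
#' @examples
#' mass_for_temperature(c(4, 20, 30, 38, 46))
#' @export
mass_for_temperature <- function(target_T) {
  if (any(!is.finite(target_T))) stop("target_T must be finite", call. = FALSE)
  ifelse(target_T < 20, 4,
         ifelse(target_T < 30, 3,
                ifelse(target_T < 38, 2, 1)))
}

#' Moles of CO2 in a vial headspace
#'
#' Ideal-gas conversion of a CO2 mixing ratio (ppm by volume) in a known
#' headspace volume to moles of CO2, at the incubation temperature.
#'
#' @param ppm CO2 concentration, micromol CO2 per mol gas.
#' @param volume_mL Headspace gas volume, mL.
#' @param temp_C Gas temperature, degC.
#' @param pressure_Pa Headspace pressure, Pa.
#' @param constants A [thermo_constants()] object.
#' @return Moles of CO2 (vectorised).
#' @examples
#' headspace_moles(500, volume_mL = 10, temp_C = 25)
#' @export
headspace_moles <- function(ppm, volume_mL, temp_C,
                            pressure_Pa = NULL,
                            constants = thermo_constants()) {
  if (is.null(pressure_Pa)) pressure_Pa <- constants$P_atm
  if (any(!is.finite(ppm)) || any(ppm < 0)) {
    stop("ppm must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(volume_mL)) || any(volume_mL <= 0)) {
    stop("headspace volume must be positive", call. = FALSE)
  }
  temp_K <- celsius_to_kelvin(temp_C)
  if (any(!is.finite(temp_K)) || any(temp_K <= 0)) {
    stop("temperature must be above absolute zero", call. = FALSE)
  }
  if (any(pressure_Pa <= 0)) stop("pressure must be positive", call. = FALSE)
  ppm * 1e-6 * pressure_Pa * volume_mL * 1e-6 / (constants$R_gas * temp_K)
}

#' Headspace volume of a sealed incubation vial
#'
#' The protocol reports only the vial volume; the gas volume is the vial
#' volume minus the volume displaced by the soil. By default the soil
#' volume is modelled as dry mass over a bulk density appropriate for
#' pumice soils (0.9 g cm^-3); an explicit `headspace_volume` column in
#' the incubations table overrides the model.
#'
#' @param vial_volume_mL Total vial volume, mL.
#' @param soil_dry_mass_g Soil dry mass, g.
#' @param soil_density_g_cm3 Assumed soil bulk density, g cm^-3.
#' @return Headspace gas volume, mL.
#' @export
headspace_volume_model <- function(vial_volume_mL, soil_dry_mass_g,
                                   soil_density_g_cm3 = 0.9) {
  v <- vial_volume_mL - soil_dry_mass_g / soil_density_g_cm3
  if (any(v <= 0)) {
    stop("soil volume exceeds vial volume; check masses and density",
         call. = FALSE)
  }
  v
}

#' Respiration rate from one vial incubation
#'
#' Converts the rise in headspace CO2 over a sealed incubation into a
#' mass-specific respiration rate: the initial concentration is
#' subtracted from the final, converted to moles with the ideal gas law
#' at the incubation temperature, and divided by soil dry mass and
#' incubation time. Negative rates (final below initial) are returned as
#' computed; downstream log-scale fitting excludes them point-wise.
#'
#' @param records A data frame of incubation records with columns
#'   `sample_id`, `measured_T` (degC), `soil_dry_mass` (g),
#'   `vial_volume` (mL), `initial_ppm`, `final_ppm`, `duration` (min),
#'   and optionally `headspace_volume` (mL).
#' @param soil_density_g_cm3 Bulk density for the headspace-volume model
#'   when `headspace_volume` is absent.
#' @param pressure_Pa Headspace pressure, Pa (defaults to the constant
#'   set's atmospheric pressure).
#' @param constants A [thermo_constants()] object.
#' @return The input data frame with an added `rate_umol_g_min` column
#'   (micromol CO2 per g dry soil per min).
#' @examples
#' rec <- data.frame(sample_id = "s1", measured_T = 25, soil_dry_mass = 4,
#'                   vial_volume = 12, headspace_volume = 10,
#'                   initial_ppm = 400, final_ppm = 900, duration = 60)
#' respiration_rate(rec)$rate_umol_g_min
#' @export
respiration_rate <- function(records, soil_density_g_cm3 = 0.9,
                             pressure_Pa = NULL,
                             constants = thermo_constants()) {
  required <- c("sample_id", "measured_T", "soil_dry_mass", "vial_volume",
                "initial_ppm", "final_ppm", "duration")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("incubations table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(records$duration <= 0)) stop("duration must be positive", call. = FALSE)
  if (any(records$soil_dry_mass <= 0)) stop("soil mass must be positive", call. = FALSE)
  if (any(records$initial_ppm < 0) || any(records$final_ppm < 0)) {
    stop("CO2 concentrations must be non-negative", call. = FALSE)
  }
  if ("headspace_volume" %in% names(records) &&
      any(is.finite(records$headspace_volume))) {
    v_head <- records$headspace_volume
    fill <- !is.finite(v_head)
    if (any(fill)) {
      v_head[fill] <- headspace_volume_model(
        records$vial_volume[fill], records$soil_dry_mass[fill],
        soil_density_g_cm3)
    }
  } else {
    v_head <- headspace_volume_model(records$vial_volume,
                                     records$soil_dry_mass,
                                     soil_density_g_cm3)
  }
  if (any(v_head > records$vial_volume)) {
    stop("headspace volume cannot exceed vial volume", call. = FALSE)
  }
  delta_ppm <- records$final_ppm - records$initial_ppm
  # signed moles: reuse the ideal-gas conversion on the magnitude
  d_mol <- sign(delta_ppm) * headspace_moles(abs(delta_ppm), v_head,
                                             records$measured_T,
                                             pressure_Pa, constants)
  records$rate_umol_g_min <-
    d_mol * 1e6 / records$soil_dry_mass / records$duration
  records
}

#' Assemble per-sample temperature-response curves
#'
#' Groups a rates table by sample, averages duplicate
#' (sample, temperature) readings with a warning, sorts each curve by
#' measured temperature, and applies the discard rule: a curve enters
#' fitting only if it has at least `min_positive` points with a strictly
#' positive rate (a fully dead sample — no CO2 released at any
#' temperature — is the canonical discard).
#'
#' @param rates A data frame with columns `sample_id`, `temperature_C`
#'   and `rate_umol_g_min` (as written by [respiration_rate()] /
#'   [pipeline_rates()]).
#' @param min_positive Minimum number of positive-rate points for a curve
#'   to be fit-eligible. The default 5 exceeds the largest parameter
#'   count plus one, so the corrected AIC is defined for every kept
#'   curve.
#' @return A list with class `response_curves`: `curves` (named list of
#'   per-sample data frames with `temperature_C`, `rate_umol_g_min`),
#'   `discarded` (logical by sample), and counts `n_kept`, `n_discarded`.
#' @export
build_curves <- function(rates, min_positive = 5) {
  required <- c("sample_id", "temperature_C", "rate_umol_g_min")
  missing_cols <- setdiff(required, names(rates))
  if (length(missing_cols)) {
    stop("rates table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(rates) == 0) {
    return(structure(list(curves = list(),
                          discarded = logical(0),
                          n_kept = 0L, n_discarded = 0L),
                     class = "response_curves"))
  }
  key <- interaction(rates$sample_id, rates$temperature_C, drop = TRUE)
  if (anyDuplicated(key)) {
    warning("duplicate (sample, temperature) entries averaged",
            call. = FALSE)
    rates <- stats::aggregate(
      rate_umol_g_min ~ sample_id + temperature_C, data = rates, FUN = mean)
  }
  ids <- sort(unique(as.character(rates$sample_id)))
  curves <- lapply(ids, function(id) {
    d <- rates[rates$sample_id == id, c("temperature_C", "rate_umol_g_min")]
    d <- d[order(d$temperature_C), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(curves) <- ids
  discarded <- vapply(curves, function(d) {
    sum(d$rate_umol_g_min > 0) < min_positive
  }, logical(1))
  structure(list(curves = curves, discarded = discarded,
                 n_kept = sum(!discarded),
                 n_discarded = sum(discarded)),
            class = "response_curves")
}

#' @export
print.response_curves <- function(x, ...) {
  cat(sprintf("Temperature-response curves: %d kept, %d discarded\n",
              x$n_kept, x$n_discarded))
  invisible(x)
}
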