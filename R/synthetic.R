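#' Factorial design specification for a synthetic study
#'
#' Describes the sampling design of a geothermal-gradient field study:
#' replicate transects running away from a heat source, sampled at fixed
#' distances, in two biomes and at two soil depths, with each sample
#' incubated at a ladder of temperatures. The defaults reproduce a
#' 3 transects x 3 distances x 2 biomes x 2 depths design (36 sampling
#' points) and a 22-temperature incubation ladder from 4 to 46 degC in
#' 2 degC steps.
#'
#' @param n_transects Number of replicate transects per biome.
#' @param distances Distances from the heat source, m.
#' @param biomes Biome labels.
#' @param depths Depth-layer labels.
#' @param incubation_temps Target incubation temperatures, degC,
#'   strictly increasing.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_transects = 3,
                        distances = c(2, 10, 30),
                        biomes = c("grassland", "kanuka"),
                        depths = c("0-50mm", "50-100mm"),
                        incubation_temps = seq(4, 46, by = 2)) {
  if (n_transects < 1 || !length(distances) || !length(biomes) ||
      !length(depths) || !length(incubation_temps)) {
    stop("design factors must all be non-empty", call. = FALSE)
  }
  if (is.unsorted(incubation_temps, strictly = TRUE)) {
    stop("incubation temperatures must be strictly increasing", call. = FALSE)
  }
  structure(list(n_transects = n_transects, distances = distances,
                 biomes = biomes, depths = depths,
                 incubation_temps = incubation_temps),
            class = "design_spec")
}

# Field-anchored means of mean environmental temperature (degC) by
# biome x depth x distance, and soil-carbon medians (% mass) by
# biome x depth. These anchor the simulated covariates to the magnitude
# and structure observed along natural geothermal gradients: MET falls
# with distance from the heat source, is higher in the shrub (kanuka)
# biome and at depth; carbon is concentrated in the topsoil.
default_met_anchors <- function() {
  data.frame(
    biome = rep(c("grassland", "kanuka"), each = 6),
    depth = rep(rep(c("0-50mm", "50-100mm"), each = 3), 2),
    distance = rep(c(2, 10, 30), 4),
    met = c(24.2, 20.9, 16.9, 31.6, 24.7, 19.6,
            35.8, 30.8, 21.8, 48.3, 38.8, 27.8)
  )
}

default_c_medians <- function() {
  data.frame(
    biome = rep(c("grassland", "kanuka"), each = 2),
    depth = rep(c("0-50mm", "50-100mm"), 2),
    c_median = c(11.07, 4.30, 22.17, 5.40)
  )
}

#' Environment model for covariate simulation
#'
#' Controls how the environmental covariates (MET, soil water content,
#' pH, C, N, C:N) are generated on top of the design. MET is anchored to
#' per-cell means, with transect-level offsets and point noise; pH
#' declines with MET (warmer, more geothermally influenced soils are
#' more acidic); C is lognormal around biome-by-depth medians; N follows
#' C through a biome-level C:N ratio; volumetric water content is drawn
#' independently. All covariates are truncated to the observed field
#' envelope so simulated soils stay within realistic ranges.
#'
#' @param met_anchors Data frame (biome, depth, distance, met) of MET
#'   cell means, degC.
#' @param met_transect_sd SD of transect-level MET offsets, degC.
#' @param met_sd SD of per-point MET noise, degC.
#' @param ph_ref Named vector of biome reference pH at the biome's mean
#'   MET.
#' @param ph_met_slope Change in pH per degC of MET; negative.
#' @param ph_sd SD of pH noise.
#' @param c_medians Data frame (biome, depth, c_median) of carbon
#'   medians, % mass.
#' @param c_sdlog Lognormal sd of carbon draws (log scale).
#' @param cn_mean Named vector of biome mean C:N ratios.
#' @param cn_sd SD of per-point C:N draws.
#' @param ws_range Range of volumetric water content, m^3 m^-3.
#' @param envelope Named list of `c(min, max)` truncation bounds for
#'   met, ph, c, n, cn.
#' @return An object of class `environment_model`.
#' @export
environment_model <- function(met_anchors = default_met_anchors(),
                              met_transect_sd = 1.5,
                              met_sd = 1.0,
                              ph_ref = c(grassland = 4.58, kanuka = 3.40),
                              ph_met_slope = -0.03,
                              ph_sd = 0.2,
                              c_medians = default_c_medians(),
                              c_sdlog = 0.35,
                              cn_mean = c(grassland = 13.7, kanuka = 21.8),
                              cn_sd = 2.0,
                              ws_range = c(0.20, 0.42),
                              envelope = list(met = c(16.9, 48.3),
                                              ph = c(3.1, 4.9),
                                              c = c(1.2, 32.3),
                                              n = c(0.07, 1.45),
                                              cn = c(12.3, 27.0))) {
  if (ph_met_slope > 0) stop("pH-MET slope must be <= 0", call. = FALSE)
  if (any(met_anchors$met <= 0) || any(c_medians$c_median <= 0)) {
    stop("anchors must be positive", call. = FALSE)
  }
  if (any(c(met_transect_sd, met_sd, ph_sd, c_sdlog, cn_sd) < 0)) {
    stop("noise scales must be non-negative", call. = FALSE)
  }
  structure(list(met_anchors = met_anchors,
                 met_transect_sd = met_transect_sd, met_sd = met_sd,
                 ph_ref = ph_ref, ph_met_slope = ph_met_slope, ph_sd = ph_sd,
                 c_medians = c_medians, c_sdlog = c_sdlog,
                 cn_mean = cn_mean, cn_sd = cn_sd,
                 ws_range = ws_range, envelope = envelope),
            class = "environment_model")
}

#' Trait model linking environment to true MMRT parameters
#'
#' Defines how the planted "true" thermal traits of each simulated soil
#' depend on its environment. The temperature optimum rises with soil
#' carbon concentration (default slope 1.3 degC per % C) and, by
#' default, does not respond to mean environmental temperature — the
#' null structure the recovery tests probe. The heat-capacity change is
#' drawn uniformly over the field-observed range, and the 25 degC rate
#' increases with carbon. Traits are converted to MMRT parameters by
#' [invert_traits()]. Measurement noise on simulated rates is
#' multiplicative lognormal, reflecting positive, heteroscedastic
#' respiration data.
#'
#' @param topt_intercept Baseline temperature optimum at zero carbon,
#'   degC.
#' @param topt_C_slope Change in T_opt per % soil carbon, degC.
#' @param topt_MET_slope Change in T_opt per degC of MET (default 0).
#' @param topt_sd SD of T_opt noise, degC.
#' @param dcp_range Range of the heat-capacity change, J mol^-1 K^-1;
#'   must lie entirely below `-R_gas`.
#' @param r25_intercept,r25_C_slope Linear link from carbon to the
#'   25 degC rate (micromol CO2 g^-1 min^-1 and per % C).
#' @param r25_sdlog Lognormal sd of R25 noise.
#' @param rate_sdlog Lognormal sd of per-incubation rate noise.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(topt_intercept = 50,
                        topt_C_slope = 1.3,
                        topt_MET_slope = 0,
                        topt_sd = 5,
                        dcp_range = c(-3400, -1100),
                        r25_intercept = 2,
                        r25_C_slope = 1.5,
                        r25_sdlog = 0.25,
                        rate_sdlog = 0.15) {
  if (max(dcp_range) >= -thermo_constants()$R_gas) {
    stop("dcp_range must lie entirely below -R_gas", call. = FALSE)
  }
  if (any(c(topt_sd, r25_sdlog, rate_sdlog) < 0)) {
    stop("noise scales must be non-negative", call. = FALSE)
  }
  structure(list(topt_intercept = topt_intercept,
                 topt_C_slope = topt_C_slope,
                 topt_MET_slope = topt_MET_slope,
                 topt_sd = topt_sd, dcp_range = sort(dcp_range),
                 r25_intercept = r25_intercept,
                 r25_C_slope = r25_C_slope,
                 r25_sdlog = r25_sdlog, rate_sdlog = rate_sdlog),
            class = "trait_model")
}

#' Generate the factorial sampling-point skeleton
#'
#' @param spec A [design_spec()].
#' @return Data frame of sampling points: `point_id`, `transect`,
#'   `distance`, `biome`, `depth` — one row per factorial combination.
#' @examples
#' nrow(generate_design(design_spec()))  # 36
#' @export
generate_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  g <- expand.grid(transect = seq_len(spec$n_transects),
                   distance = spec$distances,
                   biome = spec$biomes,
                   depth = spec$depths,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[order(g$biome, g$depth, g$transect, g$distance), ]
  g$point_id <- sprintf("%s_%s_T%d_%02dm",
                        substr(g$biome, 1, 4), gsub("mm$", "", g$depth),
                        g$transect, g$distance)
  rownames(g) <- NULL
  g[, c("point_id", "transect", "distance", "biome", "depth")]
}

clip <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

#' Simulate environmental covariates over a design
#'
#' Adds MET, Ws, pH, C, N and C:N columns to a sampling-point skeleton.
#' MET decreases with distance from the heat source within every
#' transect-by-biome-by-depth triple (enforced by ordering the drawn
#' values), pH is negatively linked to MET, and N tracks C through the
#' biome C:N ratio.
#'
#' @param points Output of [generate_design()].
#' @param model An [environment_model()].
#' @param seed Integer seed for this stage.
#' @return `points` with covariate columns `met`, `ws`, `ph`, `c_pct`,
#'   `n_pct`, `cn`.
#' @export
generate_environment <- function(points, model = environment_model(),
                                 seed = 1) {
  stopifnot(inherits(model, "environment_model"))
  set.seed(seed)
  n <- nrow(points)
  env <- model$envelope

  anchors <- merge(points, model$met_anchors,
                   by = c("biome", "depth", "distance"), sort = FALSE)
  anchors <- anchors[match(points$point_id, anchors$point_id), ]
  if (any(is.na(anchors$met))) {
    stop("no MET anchor for some biome x depth x distance cell",
         call. = FALSE)
  }
  # transect offsets shared within biome x transect
  tkey <- interaction(points$biome, points$transect, drop = TRUE)
  toff <- stats::rnorm(nlevels(tkey), 0, model$met_transect_sd)[as.integer(tkey)]
  met <- clip(anchors$met + toff + stats::rnorm(n, 0, model$met_sd), env$met)
  # enforce the geothermal-gradient ordering: MET falls with distance
  gkey <- interaction(points$biome, points$depth, points$transect, drop = TRUE)
  for (lev in levels(gkey)) {
    idx <- which(gkey == lev)
    ord <- order(points$distance[idx])
    met[idx[ord]] <- sort(met[idx], decreasing = TRUE)
  }

  ws <- stats::runif(n, model$ws_range[1], model$ws_range[2])

  met_biome_mean <- tapply(met, points$biome, mean)
  ph <- model$ph_ref[points$biome] +
    model$ph_met_slope * (met - met_biome_mean[points$biome]) +
    stats::rnorm(n, 0, model$ph_sd)
  ph <- clip(clip(unname(ph), env$ph), c(2.51, 6.99))

  cm <- merge(points[, c("point_id", "biome", "depth")], model$c_medians,
              by = c("biome", "depth"), sort = FALSE)
  cm <- cm$c_median[match(points$point_id, cm$point_id)]
  c_pct <- clip(cm * exp(stats::rnorm(n, 0, model$c_sdlog)), env$c)
  cn_draw <- clip(model$cn_mean[points$biome] +
                    stats::rnorm(n, 0, model$cn_sd), env$cn)
  n_pct <- clip(c_pct / unname(cn_draw), env$n)

  points$met <- met
  points$ws <- ws
  points$ph <- ph
  points$c_pct <- c_pct
  points$n_pct <- n_pct
  points$cn <- c_pct / n_pct
  points
}

#' Plant true MMRT parameters on each sampling point
#'
#' Draws thermal traits from the environment-linked [trait_model()] and
#' converts them to MMRT parameters via [invert_traits()], so
#' `t_opt(true params)` reproduces the drawn optimum exactly. Columns
#' are prefixed `true_` to mark them as simulation ground truth.
#'
#' @param points Output of [generate_environment()].
#' @param model A [trait_model()].
#' @param seed Integer seed for this stage.
#' @param max_retries Redraw budget for trait draws that violate the
#'   parameter preconditions.
#' @return `points` with `true_topt_C`, `true_dCp`, `true_r25`,
#'   `true_dH0`, `true_dS0`.
#' @export
assign_true_params <- function(points, model = trait_model(), seed = 1,
                               max_retries = 100) {
  stopifnot(inherits(model, "trait_model"))
  if (!all(c("met", "c_pct") %in% names(points))) {
    stop("covariates missing: run generate_environment() first", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(points)
  cc <- thermo_constants()
  draw <- function() {
    topt_C <- model$topt_intercept +
      model$topt_C_slope * points$c_pct +
      model$topt_MET_slope * points$met +
      stats::rnorm(n, 0, model$topt_sd)
    dcp <- stats::runif(n, model$dcp_range[1], model$dcp_range[2])
    r25v <- (model$r25_intercept + model$r25_C_slope * points$c_pct) *
      exp(stats::rnorm(n, 0, model$r25_sdlog))
    list(topt_C = topt_C, dcp = dcp, r25 = r25v)
  }
  d <- draw()
  bad <- !(celsius_to_kelvin(d$topt_C) > 0 & d$dcp < -cc$R_gas & d$r25 > 0)
  tries <- 0
  while (any(bad) && tries < max_retries) {
    redo <- draw()
    for (f in names(d)) d[[f]][bad] <- redo[[f]][bad]
    bad <- !(celsius_to_kelvin(d$topt_C) > 0 & d$dcp < -cc$R_gas & d$r25 > 0)
    tries <- tries + 1
  }
  if (any(bad)) stop("could not draw valid traits within retry budget",
                     call. = FALSE)
  pars <- mapply(function(to, dc, r) {
    p <- invert_traits(celsius_to_kelvin(to), dc, r, cc)
    c(p$dH0, p$dS0)
  }, d$topt_C, d$dcp, d$r25)
  points$true_topt_C <- d$topt_C
  points$true_dCp <- d$dcp
  points$true_r25 <- d$r25
  points$true_dH0 <- pars[1, ]
  points$true_dS0 <- pars[2, ]
  points
}

#' Simulate headspace incubations for every point and temperature
#'
#' For each sampling point and each target temperature, draws a measured
#' temperature (thermostat jitter), picks the protocol soil mass, draws
#' a noisy realised rate from the point's true MMRT curve, chooses an
#' incubation duration aimed at a measurable headspace CO2 rise
#' (clipped to the protocol's 52-169 min window), and writes initial and
#' final CO2 readings that are the exact inverse of
#' [respiration_rate()] — so with all noise at zero the pipeline
#' recovers the true rates to machine precision.
#'
#' @param points Output of [assign_true_params()].
#' @param spec A [design_spec()] (supplies the temperature ladder).
#' @param model A [trait_model()] (supplies the rate noise scale).
#' @param seed Integer seed for this stage.
#' @param temp_jitter_sd SD of measured-vs-target temperature, degC.
#' @param vial_volume_mL Vial volume, mL.
#' @param soil_density_g_cm3 Bulk density for the headspace-volume
#'   model.
#' @param target_dppm Aimed-for headspace CO2 rise, ppm, before the
#'   duration window is applied.
#' @param duration_range Allowed incubation durations, min.
#' @param initial_ppm_mean,initial_ppm_sd Ambient starting CO2, ppm.
#' @param constants A [thermo_constants()] object.
#' @return Data frame of incubation records (one row per point x
#'   temperature) with the columns [respiration_rate()] consumes.
#' @export
simulate_incubations <- function(points, spec = design_spec(),
                                 model = trait_model(), seed = 1,
                                 temp_jitter_sd = 0.25,
                                 vial_volume_mL = 12,
                                 soil_density_g_cm3 = 0.9,
                                 target_dppm = 500,
                                 duration_range = c(52, 169),
                                 initial_ppm_mean = 410,
                                 initial_ppm_sd = 10,
                                 constants = thermo_constants()) {
  if (!all(c("true_dH0", "true_dCp", "true_dS0") %in% names(points))) {
    stop("true parameters missing: run assign_true_params() first",
         call. = FALSE)
  }
  set.seed(seed)
  temps <- spec$incubation_temps
  recs <- merge(points[, c("point_id", "true_dH0", "true_dCp", "true_dS0")],
                data.frame(target_T = temps), by = NULL)
  recs <- recs[order(recs$point_id, recs$target_T), ]
  n <- nrow(recs)
  recs$measured_T <- recs$target_T + stats::rnorm(n, 0, temp_jitter_sd)
  recs$soil_dry_mass <- mass_for_temperature(recs$target_T)
  recs$vial_volume <- vial_volume_mL

  log_rate <- mapply(function(h, cp, s, tc) {
    mmrt_log_rate(mmrt_params(h, cp, s), celsius_to_kelvin(tc), constants)
  }, recs$true_dH0, recs$true_dCp, recs$true_dS0, recs$measured_T)
  rate <- exp(log_rate + stats::rnorm(n, 0, model$rate_sdlog))

  v_head <- headspace_volume_model(recs$vial_volume, recs$soil_dry_mass,
                                   soil_density_g_cm3)
  # moles of headspace gas per ppm of mixing ratio, at the measured T
  mol_per_ppm <- headspace_moles(rep(1, n), v_head, recs$measured_T,
                                 constants$P_atm, constants)
  # duration aimed at target_dppm: rate * mass * dur [umol] = dppm * mol_per_ppm * 1e6
  expected_rate <- exp(log_rate)
  dur <- target_dppm * mol_per_ppm * 1e6 /
    (expected_rate * recs$soil_dry_mass)
  recs$duration <- clip(dur, duration_range)

  recs$initial_ppm <- stats::rnorm(n, initial_ppm_mean, initial_ppm_sd)
  delta_ppm <- rate * recs$soil_dry_mass * recs$duration /
    (mol_per_ppm * 1e6)
  recs$final_ppm <- recs$initial_ppm + delta_ppm
  recs$sample_id <- recs$point_id
  rownames(recs) <- NULL
  recs[, c("sample_id", "target_T", "measured_T", "soil_dry_mass",
           "vial_volume", "initial_ppm", "final_ppm", "duration")]
}

#' Make one sample release no CO2
#'
#' Emulates a biologically dead sample by setting every final headspace
#' reading equal to its initial reading, so all computed rates are zero
#' and the curve is discarded by [build_curves()]. Idempotent.
#'
#' @param records Incubations table.
#' @param sample_id The sample to deaden; must exist in `records`.
#' @return The modified incubations table.
#' @export
inject_dead_sample <- function(records, sample_id) {
  if (!sample_id %in% records$sample_id) {
    stop("unknown sample_id: ", sample_id, call. = FALSE)
  }
  idx <- records$sample_id == sample_id
  records$final_ppm[idx] <- records$initial_ppm[idx]
  records
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator: design, environment, true parameters,
#' incubations, and (optionally) one dead shrub-biome sample. One global
#' seed governs a hierarchical stream — each stage receives its own
#' derived seed, so stages are reproducible in isolation and the whole
#' study is byte-for-byte deterministic.
#'
#' @param seed Global integer seed.
#' @param spec A [design_spec()].
#' @param env_model An [environment_model()].
#' @param tr_model A [trait_model()].
#' @param dead_sample If `TRUE`, one randomly chosen kanuka sample is
#'   made to release no CO2; alternatively a sample id.
#' @param ... Passed to [simulate_incubations()].
#' @return List with `points` (sampling-point table, true parameters
#'   included) and `incubations` (incubations table), plus the
#'   `dead_sample_id` used (or `NA`).
#' @export
simulate_study <- function(seed = 1, spec = design_spec(),
                           env_model = environment_model(),
                           tr_model = trait_model(),
                           dead_sample = TRUE, ...) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 4)
  points <- generate_design(spec)
  points <- generate_environment(points, env_model, seed = sub[1])
  points <- assign_true_params(points, tr_model, seed = sub[2])
  incubations <- simulate_incubations(points, spec, tr_model,
                                      seed = sub[3], ...)
  dead_id <- NA_character_
  if (isTRUE(dead_sample) || is.character(dead_sample)) {
    if (is.character(dead_sample)) {
      dead_id <- dead_sample
    } else {
      kanuka <- points$point_id[points$biome == "kanuka"]
      if (length(kanuka)) {
        set.seed(sub[4])
        dead_id <- sample(kanuka, 1)
      }
    }
    if (!is.na(dead_id)) {
      incubations <- inject_dead_sample(incubations, dead_id)
    }
  }
  list(points = points, incubations = incubations,
       dead_sample_id = dead_id)
}
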