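#' Pipeline configuration
#'
#' Assembles the nested configuration that drives the staged pipeline:
#' physical constants, the synthetic-study generator (design,
#' environment, trait models), fitting options and statistics options.
#' All defaults are valid without any user input; [read_pipeline_config()]
#' merges a YAML file over them.
#'
#' @param constants Named list of [thermo_constants()] overrides.
#' @param design Named list of [design_spec()] overrides.
#' @param environment Named list of [environment_model()] overrides.
#' @param traits Named list of [trait_model()] overrides.
#' @param fitting Named list: `min_positive` (default 5),
#'   `q10_grid` (default 5:45 degC), `soil_density` (g cm^-3).
#' @param stats Named list: `alpha` (default 0.05), `factors`,
#'   `covariates`.
#' @param dead_sample Whether the simulation deadens one kanuka sample.
#' @param seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(constants = list(), design = list(),
                            environment = list(), traits = list(),
                            fitting = list(), stats = list(),
                            dead_sample = TRUE, seed = 1) {
  fit_defaults <- list(min_positive = 5, q10_grid = 5:45,
                       soil_density = 0.9)
  stat_defaults <- list(alpha = 0.05,
                        factors = c("biome", "depth", "distance"),
                        covariates = c("met", "ws", "c_pct"))
  cfg <- list(
    constants = do.call(thermo_constants, constants),
    design = do.call(design_spec, design),
    environment = do.call(environment_model, environment),
    traits = do.call(trait_model, traits),
    fitting = utils::modifyList(fit_defaults, fitting),
    stats = utils::modifyList(stat_defaults, stats),
    dead_sample = dead_sample,
    seed = as.integer(seed)
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown fields raise an error naming the offending entry, so typos in
#' configuration files fail loudly rather than silently using defaults.
#'
#' @param path Path to a YAML file with any of the top-level blocks
#'   `constants`, `design` (under `synthetic:`), `environment`,
#'   `traits`, `fitting`, `stats`, plus `seed` and `dead_sample`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("constants", "synthetic", "fitting", "stats", "seed",
             "dead_sample")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  syn <- raw$synthetic %||% list()
  bad_syn <- setdiff(names(syn), c("design", "environment", "traits"))
  if (length(bad_syn)) {
    stop("unknown synthetic configuration field(s): ",
         paste(bad_syn, collapse = ", "), call. = FALSE)
  }
  pipeline_config(constants = raw$constants %||% list(),
                  design = syn$design %||% list(),
                  environment = syn$environment %||% list(),
                  traits = syn$traits %||% list(),
                  fitting = raw$fitting %||% list(),
                  stats = raw$stats %||% list(),
                  dead_sample = raw$dead_sample %||% TRUE,
                  seed = raw$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_columns <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

read_table <- function(x, required, what) {
  df <- if (is.character(x)) {
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  check_columns(df, required, what)
  df
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Simulate stage: write the synthetic study to CSV
#'
#' Runs [simulate_study()] at the configured seed and writes
#' `points.csv` (sampling points with environment covariates and
#' `true_`-prefixed simulation ground truth) and `incubations.csv`.
#' Column names carry their units (`met` degC, `ws` m^3 m^-3, `c_pct` /
#' `n_pct` % mass, ppm readings, minutes).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Writable output directory.
#' @return Invisibly, the simulated study list (with file paths in
#'   `paths`).
#' @export
pipeline_simulate <- function(config = pipeline_config(), out_dir = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  study <- simulate_study(seed = config$seed, spec = config$design,
                          env_model = config$environment,
                          tr_model = config$traits,
                          dead_sample = config$dead_sample,
                          soil_density_g_cm3 = config$fitting$soil_density,
                          constants = config$constants)
  paths <- c(points = file.path(out_dir, "points.csv"),
             incubations = file.path(out_dir, "incubations.csv"))
  write_table(study$points, paths["points"])
  write_table(study$incubations, paths["incubations"])
  message(sprintf(
    "simulate: seed %d -> %d points, %d incubations (%d CO2 readings)%s",
    config$seed, nrow(study$points), nrow(study$incubations),
    2L * nrow(study$incubations),
    if (is.na(study$dead_sample_id)) "" else
      paste0(", dead sample ", study$dead_sample_id)))
  study$paths <- paths
  invisible(study)
}

#' Rates stage: incubations table to respiration rates
#'
#' @param incubations Path to `incubations.csv` or a data frame.
#' @param out Optional output path for `rates.csv`.
#' @param config A [pipeline_config()].
#' @return The rates table (`sample_id`, `temperature_C`,
#'   `rate_umol_g_min`, `kept_flag`), invisibly written to `out` when
#'   given. `kept_flag` marks positive rates, the ones eligible for
#'   log-scale fitting.
#' @export
pipeline_rates <- function(incubations, out = NULL,
                           config = pipeline_config()) {
  recs <- read_table(incubations,
                     c("sample_id", "measured_T", "soil_dry_mass",
                       "vial_volume", "initial_ppm", "final_ppm",
                       "duration"),
                     "incubations")
  recs <- respiration_rate(recs,
                           soil_density_g_cm3 = config$fitting$soil_density,
                           constants = config$constants)
  rates <- data.frame(sample_id = recs$sample_id,
                      temperature_C = recs$measured_T,
                      rate_umol_g_min = recs$rate_umol_g_min,
                      kept_flag = recs$rate_umol_g_min > 0)
  message(sprintf("rates: %d incubations -> %d positive, %d non-positive",
                  nrow(rates), sum(rates$kept_flag),
                  sum(!rates$kept_flag)))
  if (!is.null(out)) write_table(rates, out)
  invisible(rates)
}

#' Fit stage: rates table to per-sample fits and model comparison
#'
#' @param rates Path to `rates.csv` or a data frame.
#' @param out_dir Optional directory for `fits.csv` and
#'   `comparison.csv`.
#' @param config A [pipeline_config()].
#' @return Invisibly, the [fit_all_curves()] result plus the
#'   `response_curves` object under `curves`.
#' @export
pipeline_fit <- function(rates, out_dir = NULL,
                         config = pipeline_config()) {
  rates <- read_table(rates,
                      c("sample_id", "temperature_C", "rate_umol_g_min"),
                      "rates")
  curves <- build_curves(rates, min_positive = config$fitting$min_positive)
  if (curves$n_kept == 0) stop("no fittable curves", call. = FALSE)
  res <- fit_all_curves(curves, min_positive = config$fitting$min_positive,
                        constants = config$constants)
  res$curves <- curves
  message(sprintf("fit: %d curves fitted, %d discarded; MMRT preferred for %d/%d",
                  curves$n_kept, curves$n_discarded,
                  sum(res$comparison$winner == "MMRT"),
                  nrow(res$comparison)))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_table(res$fits, file.path(out_dir, "fits.csv"))
    write_table(res$comparison, file.path(out_dir, "comparison.csv"))
  }
  invisible(res)
}

#' Statistics stage: treatment tables, ANOVA, stepwise, LMM
#'
#' Joins the sampling-point covariates to the per-sample fits and runs
#' the treatment-level analyses for each thermal trait: cell summary
#' tables, three-way factorial ANOVA, backwards stepwise regression on
#' (MET, Ws, C), and the transect random-intercept comparison.
#'
#' @param points Path to `points.csv` or a data frame.
#' @param fits Path to `fits.csv` or the data frame from
#'   [pipeline_fit()]`$fits`.
#' @param out_dir Optional directory for `summary.csv`, `anova.csv`,
#'   `stepwise.csv`, `lmm.csv`.
#' @param responses Trait columns to analyse.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list per response with `summary`, `anova`,
#'   `stepwise`, `lmm`, plus the joined data under `data`.
#' @export
pipeline_stats <- function(points, fits, out_dir = NULL,
                           responses = c("dH0_kJ", "dCp_kJ", "t_opt_C",
                                         "t_inf_C", "r25"),
                           config = pipeline_config()) {
  points <- read_table(points, c("point_id", "transect", "distance",
                                 "biome", "depth"), "points")
  fits <- read_table(fits, c("sample_id"), "fits")
  merged <- merge(points, fits, by.x = "point_id", by.y = "sample_id")
  if (!nrow(merged)) stop("no overlap between points and fits", call. = FALSE)
  factors <- config$stats$factors
  covars <- config$stats$covariates
  out <- list(data = merged)
  summary_rows <- list()
  anova_rows <- list()
  stepwise_rows <- list()
  lmm_rows <- list()
  for (resp in intersect(responses, names(merged))) {
    cells <- summarize_treatments(merged, resp, by = factors)
    cells$response <- resp
    summary_rows[[resp]] <- cells
    av <- three_way_anova(merged, resp, factors = factors)
    avt <- av$table
    avt$response <- resp
    avt$r_squared <- av$r_squared
    anova_rows[[resp]] <- avt
    sw <- backwards_stepwise(merged, resp, covariates = covars,
                             alpha = config$stats$alpha)
    swc <- sw$coefficients
    swc$response <- resp
    stepwise_rows[[resp]] <- swc
    lc <- lmm_compare_random(merged, resp, fixed_terms = covars,
                             group = "transect")
    lmm_rows[[resp]] <- data.frame(response = resp,
                                   aicc_random = lc$aicc_random,
                                   aicc_fixed = lc$aicc_fixed,
                                   random_improves = lc$improved)
    out[[resp]] <- list(summary = cells, anova = av, stepwise = sw,
                        lmm = lc)
  }
  tables <- list(summary = do.call(rbind, summary_rows),
                 anova = do.call(rbind, anova_rows),
                 stepwise = do.call(rbind, stepwise_rows),
                 lmm = do.call(rbind, lmm_rows))
  for (nm in names(tables)) rownames(tables[[nm]]) <- NULL
  out$tables <- tables
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(tables)) {
      write_table(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  invisible(out)
}

#' Report stage: human-readable run summary
#'
#' Prints treatment-style trait tables (means, SEs, n per cell, values
#' in degC and kJ units), the model-comparison tally, and a Q10
#' envelope table per biome on the configured reporting grid.
#'
#' @param fit_result Result of [pipeline_fit()].
#' @param stats_result Result of [pipeline_stats()].
#' @param config A [pipeline_config()].
#' @return Invisibly, the Q10 envelope table.
#' @export
pipeline_report <- function(fit_result, stats_result,
                            config = pipeline_config()) {
  cmp <- fit_result$comparison
  cat(sprintf("Fitted curves: %d (MMRT preferred by AICc: %d, min delta %.1f)\n\n",
              nrow(cmp), sum(cmp$winner == "MMRT"), min(cmp$delta)))
  tab <- stats_result$tables$summary
  for (resp in unique(tab$response)) {
    cat(sprintf("== %s (mean +/- SE per cell) ==\n", resp))
    cells <- tab[tab$response == resp,
                 setdiff(names(tab), "response")]
    cells$mean <- round(cells$mean, 1)
    cells$se <- round(cells$se, 1)
    print(cells, row.names = FALSE)
    cat("\n")
  }
  merged <- stats_result$data
  groups <- merged$biome[match(names(fit_result$mmrt), merged$point_id)]
  env <- q10_envelope(fit_result$mmrt, groups,
                      T_grid_C = config$fitting$q10_grid)
  cat("== Q10 envelope (per biome) ==\n")
  show <- env[env$temperature_C %in% seq(5, 45, by = 10), ]
  show$q10_mean <- round(show$q10_mean, 2)
  show$q10_se <- round(show$q10_se, 3)
  print(show, row.names = FALSE)
  invisible(env)
}

#' Run the full pipeline end to end
#'
#' simulate -> rates -> fit -> stats (-> report), each stage writing its
#' CSV outputs under `out_dir`. Composing the stages by hand on the
#' written files gives identical results — each stage is a pure function
#' of its input table.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param report Print the human-readable summary.
#' @return Invisibly, a list with `study`, `rates`, `fit`, `stats`.
#' @export
pipeline_all <- function(config = pipeline_config(), out_dir = ".",
                         report = FALSE) {
  study <- pipeline_simulate(config, out_dir)
  rates <- pipeline_rates(study$incubations,
                          out = file.path(out_dir, "rates.csv"),
                          config = config)
  fit <- pipeline_fit(rates, out_dir = out_dir, config = config)
  stats <- pipeline_stats(study$points, fit$fits, out_dir = out_dir,
                          config = config)
  if (report) pipeline_report(fit, stats, config)
  invisible(list(study = study, rates = rates, fit = fit, stats = stats))
}
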