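#' Published treatment-table cell values from a geothermal field study
#'
#' Per-cell means and standard errors (n = 3 transects per cell) of the
#' environmental covariates and of the fitted MMRT parameters/traits
#' from a geothermal-gradient field study, keyed by biome x depth x
#' distance. These printed cells are inputs: [marginal_means()] over
#' them reproduces the study's reported marginal summaries, and the
#' synthetic-data generator anchors its covariate structure to them.
#'
#' @param which `"environment"` (MET, Ws, pH, C, N, C:N) or `"mmrt"`
#'   (dH0, dCp, T_inf, T_opt, R25). Units are in the column names
#'   (degC, kJ mol^-1 (K^-1), % mass, micromol CO2 g^-1 min^-1).
#' @return Data frame of cell means and SEs.
#' @examples
#' cells <- field_cells("mmrt")
#' # marginal heat-capacity change per biome, as the mean of cell means
#' marginal_means(data.frame(cells[1:3], mean = cells$dCp_kJ,
#'                           se = cells$dCp_kJ_se, n = 3), by = "biome")
#' @export
field_cells <- function(which = c("environment", "mmrt")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("field_",
                          if (which == "environment") "environment_cells"
                          else "mmrt_cells", ".csv"),
                   package = "thermoresp", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
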