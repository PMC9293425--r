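#' Treatment-cell summary table
#'
#' Cell means, standard errors (sd/sqrt(n)) and counts of one variable
#' over the crossing of the given treatment factors — the structure of a
#' field-study treatment table.
#'
#' @param data Data frame holding the variable and the factors.
#' @param variable Name of the numeric column to summarise.
#' @param by Character vector of grouping-factor column names.
#' @return Data frame with the factor columns plus `mean`, `se`, `n`.
#'   Empty cells are absent (reported as missing, not an error).
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' summarize_treatments(d, "y", by = "g")
#' @export
summarize_treatments <- function(data, variable,
                                 by = c("biome", "depth", "distance")) {
  missing_cols <- setdiff(c(variable, by), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- data[[variable]]
  key <- data[by]
  agg <- stats::aggregate(x, by = key, FUN = function(v) {
    v <- v[is.finite(v)]
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
      n = length(v))
  })
  out <- cbind(agg[by], as.data.frame(agg$x))
  names(out) <- c(by, "mean", "se", "n")
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marginal means from a cell-summary table
#'
#' Unweighted mean of cell means over the cells sharing each level of
#' the retained factors — the correct marginal for a balanced design,
#' and the convention used in field treatment tables. The reported `se`
#' is the standard error of the cell means being averaged.
#'
#' @param cells Output of [summarize_treatments()].
#' @param by Factor(s) to retain; all other factor columns are averaged
#'   over.
#' @return Data frame with the retained factor columns plus
#'   `mean`, `se`, `n_cells`.
#' @export
marginal_means <- function(cells, by) {
  factor_cols <- setdiff(names(cells), c("mean", "se", "n"))
  if (!all(by %in% factor_cols)) {
    stop("marginal factors must be columns of the cell table", call. = FALSE)
  }
  agg <- stats::aggregate(cells$mean, by = cells[by], FUN = function(v) {
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  out <- cbind(agg[by], as.data.frame(agg$x))
  names(out) <- c(by, "mean", "se", "n_cells")
  rownames(out) <- NULL
  out
}

#' Three-way factorial ANOVA with sequential sums of squares
#'
#' Full-factorial linear model of a response on three treatment factors
#' with sequential (Type I) sums of squares, taken in the fixed order
#' main effects, two-way interactions, three-way interaction. Because
#' one discarded sample can unbalance the design, the order is fixed
#' and stated rather than left to chance.
#'
#' @param data Data frame.
#' @param response Name of the numeric response column.
#' @param factors Character vector of exactly three factor column
#'   names, in the order in which the sequential decomposition is
#'   taken.
#' @return List of class `anova3`: `table` (term, df, ss, ms, F, p),
#'   `r_squared`, and the underlying `lm` fit.
#' @export
three_way_anova <- function(data, response,
                            factors = c("biome", "depth", "distance")) {
  if (length(factors) != 3) stop("exactly three factors required", call. = FALSE)
  missing_cols <- setdiff(c(response, factors), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data
  for (f in factors) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) < 2) {
      stop("factor ", f, " needs at least 2 levels", call. = FALSE)
    }
  }
  d <- d[is.finite(d[[response]]), , drop = FALSE]
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = " * ")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    warning("aliased terms (empty cells) dropped from the model",
            call. = FALSE)
  }
  at <- stats::anova(fit)
  tab <- data.frame(term = rownames(at), df = at$Df, ss = at$`Sum Sq`,
                    ms = at$`Mean Sq`, F = at$`F value`,
                    p = at$`Pr(>F)`)
  rownames(tab) <- NULL
  ss_tot <- sum(tab$ss)
  r2 <- 1 - tab$ss[tab$term == "Residuals"] / ss_tot
  structure(list(table = tab, r_squared = r2, fit = fit), class = "anova3")
}

#' @export
print.anova3 <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("R-squared: %.3f\n", x$r_squared))
  invisible(x)
}

#' Backwards stepwise regression from a full interaction model
#'
#' Starts from the full model containing the three-way interaction of
#' the supplied covariates and drops, one term at a time, the least
#' significant currently droppable term (highest F-test p-value above
#' `alpha`). Marginality is respected throughout — an interaction is
#' never retained without its constituent main effects, and a term is
#' only droppable while no higher-order term contains it (this is
#' `drop1()`'s rule). Stops when every remaining term is significant or
#' only the intercept remains.
#'
#' @param data Data frame of response and covariates.
#' @param response Name of the response column.
#' @param covariates Character vector of covariate names forming the
#'   full crossed model.
#' @param alpha Retention threshold for the per-term F-test p-value.
#' @return List of class `stepwise_fit`: `fit` (final `lm`),
#'   `retained` (term labels), `coefficients` (estimate, se, t, p),
#'   `anova` (per-term F tests of the final model) and `trace`
#'   (data frame of the elimination path: step, dropped term,
#'   p-value).
#' @export
backwards_stepwise <- function(data, response,
                               covariates = c("met", "ws", "c_pct"),
                               alpha = 0.05) {
  missing_cols <- setdiff(c(response, covariates), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[is.finite(data[[response]]), , drop = FALSE]
  n_terms_full <- 2^length(covariates) - 1
  if (nrow(d) <= n_terms_full + 1) {
    stop("too few observations for the full model", call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(covariates, collapse = " * ")))
  fit <- stats::lm(fml, data = d)
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p_value = numeric(0))
  step <- 0L
  repeat {
    if (!length(attr(stats::terms(fit), "term.labels"))) break
    d1 <- stats::drop1(fit, test = "F")
    cand <- d1[-1, , drop = FALSE]  # first row is <none>
    p <- cand$`Pr(>F)`
    if (!length(p) || all(p <= alpha, na.rm = TRUE)) break
    worst <- rownames(cand)[which.max(p)]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = worst,
                                     p_value = max(p, na.rm = TRUE)))
    fit <- stats::update(fit, stats::as.formula(paste(". ~ . -", worst)))
  }
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "se", "t", "p")
  coefs$term <- rownames(coefs)
  rownames(coefs) <- NULL
  final_terms <- attr(stats::terms(fit), "term.labels")
  fit_anova <- if (length(final_terms)) {
    at <- stats::anova(fit)
    data.frame(term = rownames(at), df = at$Df, ss = at$`Sum Sq`,
               F = at$`F value`, p = at$`Pr(>F)`)
  } else {
    data.frame(term = character(0), df = integer(0), ss = numeric(0),
               F = numeric(0), p = numeric(0))
  }
  rownames(fit_anova) <- NULL
  structure(list(fit = fit, retained = final_terms,
                 coefficients = coefs[, c("term", "estimate", "se", "t", "p")],
                 anova = fit_anova, trace = trace),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Backwards stepwise regression\n")
  cat("Retained terms:",
      if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  print(x$coefficients, row.names = FALSE)
  if (nrow(x$trace)) {
    cat("Elimination trace:\n")
    print(x$trace, row.names = FALSE)
  }
  invisible(x)
}

#' Average marginal slope of a fitted model in one covariate
#'
#' The model-implied slope of the response with respect to one
#' covariate, averaged over the observed data: the mean of
#' \eqn{\partial \hat y / \partial x} across rows. For a model in which
#' the covariate enters only as a main effect this is exactly its
#' coefficient; in the presence of interactions the main-effect
#' coefficient is the slope at zero of the interacting covariates —
#' usually far outside the data — while the average marginal slope is
#' the meaningful summary. Computed by central differences on the
#' model predictions, which is exact for models linear in the
#' covariate.
#'
#' @param fit An `lm` fit or a [backwards_stepwise()] result.
#' @param data Data frame over which to average (the fitting data).
#' @param covariate Name of the covariate.
#' @param h Half-width of the difference step, in covariate units.
#' @return The average marginal slope (response units per covariate
#'   unit).
#' @export
marginal_slope <- function(fit, data, covariate, h = 1) {
  if (inherits(fit, "stepwise_fit")) fit <- fit$fit
  stopifnot(inherits(fit, "lm"))
  up <- data
  dn <- data
  up[[covariate]] <- up[[covariate]] + h
  dn[[covariate]] <- dn[[covariate]] - h
  mean((stats::predict(fit, newdata = up) -
          stats::predict(fit, newdata = dn)) / (2 * h))
}

#' Proportion of variance explained by a single covariate
#'
#' R-squared of the simple linear regression of the response on one
#' covariate; identical to the squared Pearson correlation.
#'
#' @param data Data frame.
#' @param response Name of the response column.
#' @param covariate Name of the covariate column.
#' @return A proportion in `[0, 1]`.
#' @export
variance_explained <- function(data, response, covariate) {
  missing_cols <- setdiff(c(response, covariate), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- data[[covariate]]
  y <- data[[response]]
  keep <- is.finite(x) & is.finite(y)
  if (stats::var(x[keep]) == 0) {
    stop("covariate has zero variance", call. = FALSE)
  }
  summary(stats::lm(y[keep] ~ x[keep]))$r.squared
}

lmm_aicc_from_loglik <- function(ll, n, k) {
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Random-intercept mixed model with AICc
#'
#' Gaussian random-intercept model fitted by maximum likelihood (ML, not
#' REML, so information criteria are comparable across fixed-effect
#' structures). The AICc parameter count is the number of fixed-effect
#' coefficients plus two variance components.
#'
#' @param data Data frame.
#' @param response Name of the response column.
#' @param fixed_terms Character vector of fixed-effect terms (may be
#'   empty for an intercept-only model).
#' @param group Name of the grouping column for the random intercept.
#' @return List of class `lmm_fit`: `fixed` (coefficient table),
#'   `sigma_within`, `sigma_between`, `logLik`, `aicc`, `n`, and the
#'   underlying `nlme::lme` fit.
#' @export
lmm_random_intercept <- function(data, response, fixed_terms = character(0),
                                 group = "transect") {
  missing_cols <- setdiff(c(response, fixed_terms, group), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[is.finite(data[[response]]), , drop = FALSE]
  d[[group]] <- factor(d[[group]])
  if (nlevels(d[[group]]) < 2) {
    stop("need at least 2 groups for a random intercept", call. = FALSE)
  }
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs))
  ran <- stats::as.formula(paste("~ 1 |", group))
  fit <- nlme::lme(fixed = fml, random = ran, data = d, method = "ML")
  vc <- nlme::VarCorr(fit)
  sigma_between <- as.numeric(vc["(Intercept)", "StdDev"])
  sigma_within <- fit$sigma
  ll <- as.numeric(stats::logLik(fit))
  n <- nrow(d)
  k <- length(nlme::fixef(fit)) + 2L
  structure(list(fixed = summary(fit)$tTable,
                 sigma_within = sigma_within,
                 sigma_between = sigma_between,
                 logLik = ll, aicc = lmm_aicc_from_loglik(ll, n, k),
                 n = n, k = k, fit = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept model (ML): n = %d, AICc = %.2f\n", x$n, x$aicc))
  cat(sprintf("  sigma between groups = %.4g, within = %.4g\n",
              x$sigma_between, x$sigma_within))
  invisible(x)
}

#' Does a transect random intercept improve the model?
#'
#' Fits the same fixed-effect structure with and without the random
#' intercept (the fixed-only model by ordinary least squares, which is
#' the ML fit) and compares AICc. Mirrors the design question of whether
#' spatial autocorrelation along transects needs to be modelled.
#'
#' @inheritParams lmm_random_intercept
#' @return List: `aicc_random`, `aicc_fixed`, `improved` (`TRUE` if the
#'   random-intercept model has lower AICc), and the two fits.
#' @export
lmm_compare_random <- function(data, response,
                               fixed_terms = character(0),
                               group = "transect") {
  re <- lmm_random_intercept(data, response, fixed_terms, group)
  d <- data[is.finite(data[[response]]), , drop = FALSE]
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs))
  lmfit <- stats::lm(fml, data = d)
  n <- nrow(d)
  k <- length(stats::coef(lmfit)) + 1L
  aicc_fixed <- lmm_aicc_from_loglik(as.numeric(stats::logLik(lmfit)), n, k)
  list(aicc_random = re$aicc, aicc_fixed = aicc_fixed,
       improved = re$aicc < aicc_fixed,
       random_fit = re, fixed_fit = lmfit)
}
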