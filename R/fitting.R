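#' Corrected Akaike information criterion from a residual sum of squares
#'
#' Gaussian-likelihood AICc: `n*log(rss/n) + 2k + 2k(k+1)/(n-k-1)`,
#' where `k` counts all estimated quantities including the residual
#' variance. Comparable across models only when both are fit to the same
#' response on the same scale; both fitters here work on the log-rate
#' scale.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param k Number of estimated parameters including the residual
#'   variance.
#' @return The corrected AIC.
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) {
    stop("AICc undefined: need n > k + 1", call. = FALSE)
  }
  if (rss <= 0) stop("rss must be positive", call. = FALSE)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Shared log-scale least-squares core. X must include any intercept
# column explicitly. Returns coefficients, covariance, rss, sigma2.
log_ols <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("singular design: temperatures do not span the model", call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  resid <- y - X %*% beta
  rss <- sum(resid^2)
  df <- length(y) - ncol(X)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qx))
  list(beta = as.numeric(beta), vcov = sigma2 * XtX_inv,
       rss = rss, sigma2 = sigma2, fitted = as.numeric(X %*% beta))
}

curve_positive_points <- function(curve, min_positive) {
  keep <- is.finite(curve$rate_umol_g_min) & curve$rate_umol_g_min > 0
  if (sum(keep) < min_positive) {
    stop(sprintf("curve has %d positive-rate points; need at least %d",
                 sum(keep), min_positive), call. = FALSE)
  }
  curve[keep, , drop = FALSE]
}

#' Fit macromolecular rate theory to a temperature-response curve
#'
#' The MMRT log rate is exactly linear in its three parameters, so the
#' fit is ordinary least squares of `log(rate) - log(kB*T/h)` on the
#' three basis columns for dH0, dCp and dS0 — closed-form, with the
#' exact solution of the nonlinear problem on the log scale.
#' Non-positive rates are excluded point-wise. Derived traits (T_opt,
#' T_inf, R25, dG0) carry delta-method standard errors propagated
#' through the parameter covariance.
#'
#' @param curve Data frame with `temperature_C` and `rate_umol_g_min`
#'   (one sample's curve, e.g. one element of [build_curves()]).
#' @param sample_id Optional identifier carried into the result.
#' @param min_positive Minimum positive-rate points required.
#' @param constants A [thermo_constants()] object.
#' @return An object of class `mmrt_fit`: parameters, covariance
#'   (order dH0, dCp, dS0), `n_points`, `rss`, `sigma2`, `aicc`
#'   (k = 4), `traits` (with `se` columns) and the temperatures used.
#' @export
fit_mmrt <- function(curve, sample_id = NA_character_, min_positive = 5,
                     constants = thermo_constants()) {
  curve <- curve_positive_points(curve, min_positive)
  temp_K <- celsius_to_kelvin(curve$temperature_C)
  R <- constants$R_gas
  T0 <- constants$T0
  y <- log(curve$rate_umol_g_min) -
    log(constants$k_B * temp_K / constants$h_planck)
  X <- cbind(dH0 = -1 / (R * temp_K),
             dCp = -(temp_K - T0) / (R * temp_K) + log(temp_K / T0) / R,
             dS0 = rep(1 / R, length(temp_K)))
  sol <- log_ols(X, y)
  params <- mmrt_params(sol$beta[1], sol$beta[2], sol$beta[3])
  n <- length(y)
  fit <- structure(list(
    sample_id = sample_id, model = "MMRT", params = params,
    coef = c(dH0 = sol$beta[1], dCp = sol$beta[2], dS0 = sol$beta[3]),
    vcov = sol$vcov, n_points = n, rss = sol$rss, sigma2 = sol$sigma2,
    aicc = aicc(sol$rss, n, k = 4L),
    temperatures_C = curve$temperature_C,
    constants = constants), class = "mmrt_fit")
  fit$traits <- mmrt_fit_traits(fit)
  fit
}

# Traits + delta-method SEs for an MMRT fit. Traits requiring
# dCp < -R are reported as NA (with a warning) rather than failing the
# whole fit, since noisy curves without an in-range optimum are data.
mmrt_fit_traits <- function(fit) {
  cc <- fit$constants
  p <- fit$params
  has_opt <- p$dCp < -cc$R_gas
  out <- data.frame(trait = c("t_opt_C", "t_inf_C", "r25", "dG0_kJ"),
                    estimate = NA_real_, se = NA_real_)
  if (has_opt) {
    out$estimate <- c(kelvin_to_celsius(t_opt(p, cc)),
                      kelvin_to_celsius(t_inf(p, cc)),
                      r25(p, cc), dG0(p, cc) / 1000)
  } else {
    warning("fitted dCp >= -R_gas: no temperature optimum; ",
            "T_opt and T_inf undefined", call. = FALSE)
    out$estimate[3:4] <- c(r25(p, cc), dG0(p, cc) / 1000)
  }
  out$se <- vapply(out$trait, function(tr) {
    tryCatch(trait_se_delta(fit, tr), error = function(e) NA_real_)
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Delta-method standard error of a derived thermal trait
#'
#' Propagates the MMRT parameter covariance through the analytic
#' gradient of the trait's closed form with respect to
#' (dH0, dCp, dS0). T_opt and T_inf do not depend on dS0 (zero
#' partial), and R25 does not depend on dCp.
#'
#' @param fit An `mmrt_fit` object.
#' @param trait One of `"t_opt_C"`, `"t_inf_C"`, `"r25"`, `"dG0_kJ"`.
#' @return The standard error, in the trait's reporting units.
#' @export
trait_se_delta <- function(fit, trait = c("t_opt_C", "t_inf_C", "r25",
                                          "dG0_kJ")) {
  trait <- match.arg(trait)
  cc <- fit$constants
  p <- fit$params
  R <- cc$R_gas
  T0 <- cc$T0
  g <- switch(trait,
    t_opt_C = {
      if (p$dCp >= -R) stop("T_opt undefined at fitted parameters",
                            call. = FALSE)
      N <- p$dH0 - p$dCp * T0
      D <- -p$dCp - R
      c(1 / D, (N - T0 * D) / D^2, 0)
    },
    t_inf_C = {
      if (p$dCp >= 0) stop("T_inf undefined at fitted parameters",
                           call. = FALSE)
      N <- p$dH0 - p$dCp * T0
      s <- sqrt(-p$dCp * R)
      D <- -p$dCp + s
      dD_dcp <- -1 - R / (2 * s)
      c(1 / D, (-T0 * D - N * dD_dcp) / D^2, 0)
    },
    r25 = {
      r <- r25(p, cc)
      c(-r / (R * T0), 0, r / R)
    },
    dG0_kJ = c(1, 0, -T0) / 1000
  )
  sqrt(as.numeric(t(g) %*% fit$vcov %*% g))
}

#' Fit the Lloyd & Taylor model to a temperature-response curve
#'
#' Linear least squares of `log(rate)` on the Lloyd & Taylor basis
#' `1/56.02 - 1/(T - 227.13)`, yielding (lnR10, E0). Residual-variance
#' and AICc conventions match [fit_mmrt()] (both on the log-rate
#' scale), so the two criteria are directly comparable.
#'
#' @inheritParams fit_mmrt
#' @return An object of class `lt_fit` with fields paralleling
#'   `mmrt_fit` (k = 3 for AICc).
#' @export
fit_lloyd_taylor <- function(curve, sample_id = NA_character_,
                             min_positive = 5,
                             constants = thermo_constants()) {
  curve <- curve_positive_points(curve, min_positive)
  temp_K <- celsius_to_kelvin(curve$temperature_C)
  if (any(temp_K <= constants$lt_T0_offset)) {
    stop("temperatures at or below the Lloyd & Taylor zero-rate offset",
         call. = FALSE)
  }
  y <- log(curve$rate_umol_g_min)
  X <- cbind(lnR10 = rep(1, length(temp_K)),
             E0 = 1 / constants$lt_ref_span -
               1 / (temp_K - constants$lt_T0_offset))
  sol <- log_ols(X, y)
  n <- length(y)
  structure(list(
    sample_id = sample_id, model = "LT",
    params = lt_params(sol$beta[1], sol$beta[2]),
    coef = c(lnR10 = sol$beta[1], E0 = sol$beta[2]),
    vcov = sol$vcov, n_points = n, rss = sol$rss, sigma2 = sol$sigma2,
    aicc = aicc(sol$rss, n, k = 3L),
    temperatures_C = curve$temperature_C,
    constants = constants), class = "lt_fit")
}

#' @export
print.mmrt_fit <- function(x, ...) {
  cat(sprintf("MMRT fit%s: n = %d, AICc = %.2f\n",
              if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
              x$n_points, x$aicc))
  cat(sprintf("  dH0 = %.1f kJ/mol, dCp = %.2f kJ/mol/K, dS0 = %.1f J/mol/K\n",
              x$coef[1] / 1000, x$coef[2] / 1000, x$coef[3]))
  print(x$traits, row.names = FALSE)
  invisible(x)
}

#' @export
print.lt_fit <- function(x, ...) {
  cat(sprintf("Lloyd & Taylor fit%s: n = %d, AICc = %.2f\n",
              if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
              x$n_points, x$aicc))
  cat(sprintf("  R10 = %.3g, E0 = %.1f K\n", exp(x$coef[1]), x$coef[2]))
  invisible(x)
}

#' Compare MMRT and Lloyd & Taylor fits of one curve by AICc
#'
#' @param fit_m An `mmrt_fit`.
#' @param fit_l An `lt_fit` of the same points.
#' @return A one-row data frame: `sample_id`, `aicc_mmrt`, `aicc_lt`,
#'   `delta` (`aicc_lt - aicc_mmrt`) and `winner` (`"MMRT"` iff
#'   `delta > 0`).
#' @export
compare_models <- function(fit_m, fit_l) {
  stopifnot(inherits(fit_m, "mmrt_fit"), inherits(fit_l, "lt_fit"))
  if (fit_m$n_points != fit_l$n_points ||
      !isTRUE(all.equal(fit_m$temperatures_C, fit_l$temperatures_C))) {
    stop("fits were made on different point sets; comparison refused",
         call. = FALSE)
  }
  delta <- fit_l$aicc - fit_m$aicc
  data.frame(sample_id = fit_m$sample_id,
             aicc_mmrt = fit_m$aicc, aicc_lt = fit_l$aicc,
             delta = delta,
             winner = if (delta > 0) "MMRT" else "LT")
}

#' Fit both models to every fit-eligible curve
#'
#' @param curves A `response_curves` object from [build_curves()].
#' @param min_positive Minimum positive-rate points.
#' @param constants A [thermo_constants()] object.
#' @return List with `mmrt` and `lt` (named lists of fit objects for
#'   kept curves), `comparison` (data frame from [compare_models()]),
#'   and `fits` — a tidy per-sample data frame of parameters (kJ
#'   units), traits (degC) and fit summaries.
#' @export
fit_all_curves <- function(curves, min_positive = 5,
                           constants = thermo_constants()) {
  stopifnot(inherits(curves, "response_curves"))
  kept <- names(curves$curves)[!curves$discarded]
  if (!length(kept)) stop("no fittable curves", call. = FALSE)
  mmrt <- lapply(kept, function(id) {
    fit_mmrt(curves$curves[[id]], sample_id = id,
             min_positive = min_positive, constants = constants)
  })
  lt <- lapply(kept, function(id) {
    fit_lloyd_taylor(curves$curves[[id]], sample_id = id,
                     min_positive = min_positive, constants = constants)
  })
  names(mmrt) <- names(lt) <- kept
  comparison <- do.call(rbind, Map(compare_models, mmrt, lt))
  rownames(comparison) <- NULL
  fits <- do.call(rbind, lapply(kept, function(id) {
    fm <- mmrt[[id]]
    fl <- lt[[id]]
    tr <- fm$traits
    est <- function(nm) tr$estimate[tr$trait == nm]
    se <- function(nm) tr$se[tr$trait == nm]
    data.frame(
      sample_id = id,
      n_points = fm$n_points,
      dH0_kJ = fm$coef[["dH0"]] / 1000,
      dH0_kJ_se = sqrt(fm$vcov[1, 1]) / 1000,
      dCp_kJ = fm$coef[["dCp"]] / 1000,
      dCp_kJ_se = sqrt(fm$vcov[2, 2]) / 1000,
      dS0_J = fm$coef[["dS0"]],
      dS0_J_se = sqrt(fm$vcov[3, 3]),
      t_opt_C = est("t_opt_C"), t_opt_C_se = se("t_opt_C"),
      t_inf_C = est("t_inf_C"), t_inf_C_se = se("t_inf_C"),
      r25 = est("r25"), r25_se = se("r25"),
      rss_mmrt = fm$rss, aicc_mmrt = fm$aicc,
      lnR10 = fl$coef[["lnR10"]], E0_K = fl$coef[["E0"]],
      E0_K_se = sqrt(fl$vcov[2, 2]),
      rss_lt = fl$rss, aicc_lt = fl$aicc)
  }))
  rownames(fits) <- NULL
  list(mmrt = mmrt, lt = lt, comparison = comparison, fits = fits)
}

#' Treatment-level Q10 mean and standard-error envelope
#'
#' Evaluates the MMRT Q10 of every replicate fit on a temperature grid
#' and summarises per treatment group: the envelope mean at each grid
#' temperature is the arithmetic mean of the per-replicate Q10 values
#' and the envelope half-width is their standard error.
#'
#' @param fits Named list of `mmrt_fit` objects.
#' @param groups Factor or character vector, one group label per fit.
#' @param T_grid_C Reporting temperatures, degC.
#' @return Data frame: `group`, `temperature_C`, `q10_mean`, `q10_se`,
#'   `n`.
#' @export
q10_envelope <- function(fits, groups, T_grid_C = 5:45) {
  if (!length(fits)) stop("empty fit collection", call. = FALSE)
  if (length(groups) != length(fits)) {
    stop("one group label required per fit", call. = FALSE)
  }
  groups <- as.character(groups)
  if (any(table(groups) < 2)) {
    stop("each treatment group needs at least 2 replicate fits",
         call. = FALSE)
  }
  out <- lapply(unique(groups), function(g) {
    members <- fits[groups == g]
    q <- vapply(members, function(f) {
      q10_mmrt(f$params, celsius_to_kelvin(T_grid_C), f$constants)
    }, numeric(length(T_grid_C)))
    data.frame(group = g, temperature_C = T_grid_C,
               q10_mean = rowMeans(q),
               q10_se = apply(q, 1, stats::sd) / sqrt(ncol(q)),
               n = ncol(q))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
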