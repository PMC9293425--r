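test_that("AICc formula matches hand arithmetic and its limits", {
  expect_equal(aicc(1, 22, 4), 22 * log(1 / 22) + 8 + 40 / 17)
  expect_equal(aicc(1, 22, 4), -57.65, tolerance = 1e-3)
  # equal rss, fewer parameters -> lower criterion
  expect_lt(aicc(2, 22, 3), aicc(2, 22, 4))
  # correction vanishes as n grows
  aic <- function(rss, n, k) n * log(rss / n) + 2 * k
  expect_lt(abs(aicc(5, 1e6, 4) - aic(5, 1e6, 4)), 1e-4)
  expect_error(aicc(1, 5, 4), "n > k")
})

test_that("noiseless curves are recovered to numerical precision", {
  p <- invert_traits(340, -2100, 15)
  fit <- fit_mmrt(make_mmrt_curve(p))
  expect_equal(fit$coef[["dH0"]], p$dH0, tolerance = 1e-9)
  expect_equal(fit$coef[["dCp"]], p$dCp, tolerance = 1e-9)
  expect_equal(fit$coef[["dS0"]], p$dS0, tolerance = 1e-9)

  lp <- lt_params(lnR10 = 1.4, E0 = 310)
  lfit <- fit_lloyd_taylor(make_lt_curve(lp))
  expect_equal(lfit$coef[["lnR10"]], 1.4, tolerance = 1e-9)
  expect_equal(lfit$coef[["E0"]], 310, tolerance = 1e-9)
})

test_that("log-space OLS equals an independent nonlinear optimiser", {
  skip_if_not_installed("minpack.lm")
  set.seed(31)
  p <- invert_traits(335, -1800, 12)
  curve <- make_mmrt_curve(p, sdlog = 0.15)
  fit <- fit_mmrt(curve)
  cc <- thermo_constants()
  tk <- curve$temperature_C + 273.15
  resid_fn <- function(par) {
    log(curve$rate_umol_g_min) -
      mmrt_log_rate(mmrt_params(par[1], par[2], par[3]), tk, cc)
  }
  nls <- minpack.lm::nls.lm(par = c(5e4, -1500, 20), fn = resid_fn)
  expect_equal(unname(fit$coef), unname(coef(nls)), tolerance = 1e-6)
  expect_equal(fit$rss, sum(residuals(nls)^2), tolerance = 1e-9)
})

test_that("fitter guards: too few positives, singular design", {
  flat <- data.frame(temperature_C = rep(20, 8),
                     rate_umol_g_min = exp(rnorm(8)))
  expect_error(fit_mmrt(flat), "singular")
  few <- data.frame(temperature_C = seq(4, 16, 2),
                    rate_umol_g_min = c(1, 2, 1, -1, 0, 0, 0))
  expect_error(fit_mmrt(few), "positive-rate")
  # non-positive rates dropped point-wise, not fatally
  mix <- make_mmrt_curve(invert_traits(330, -2000, 10))
  mix$rate_umol_g_min[c(3, 9)] <- c(0, -0.5)
  expect_equal(fit_mmrt(mix)$n_points, 20)
})

test_that("Wald intervals for dCp reach nominal-ish coverage", {
  set.seed(32)
  true <- invert_traits(65 + 273.15, -2000, 20)
  cover <- 0
  for (i in 1:200) {
    f <- fit_mmrt(make_mmrt_curve(true, sdlog = 0.15))
    half <- 1.96 * sqrt(f$vcov[2, 2])
    if (abs(f$coef[["dCp"]] + 2000) <= half) cover <- cover + 1
  }
  expect_gte(cover / 200, 0.88)
})

test_that("E0 is recovered within its interval on noisy LT-truth data", {
  set.seed(33)
  lp <- lt_params(1.2, 320)
  cover <- 0
  for (i in 1:200) {
    f <- fit_lloyd_taylor(make_lt_curve(lp, sdlog = 0.15))
    half <- 1.96 * sqrt(f$vcov[2, 2])
    if (abs(f$coef[["E0"]] - 320) <= half) cover <- cover + 1
  }
  expect_gte(cover / 200, 0.88)
})

test_that("model comparison prefers the generating model", {
  # MMRT truth with an optimum inside the measured range
  set.seed(34)
  wins <- 0
  for (i in 1:40) {
    p <- invert_traits(runif(1, 301, 313), runif(1, -3400, -1600),
                       exp(runif(1, 1, 3)))
    curve <- make_mmrt_curve(p, sdlog = 0.15)
    cmp <- compare_models(fit_mmrt(curve), fit_lloyd_taylor(curve))
    if (cmp$winner == "MMRT") wins <- wins + 1
  }
  expect_gte(wins / 40, 0.9)

  # LT truth (no optimum in range): LT wins on most curves
  set.seed(35)
  lt_wins <- 0
  for (i in 1:40) {
    curve <- make_lt_curve(lt_params(runif(1, 0, 2), runif(1, 250, 400)),
                           sdlog = 0.15)
    cmp <- compare_models(fit_mmrt(curve), fit_lloyd_taylor(curve))
    if (cmp$winner == "LT") lt_wins <- lt_wins + 1
  }
  expect_gt(lt_wins / 40, 0.5)

  # curvature misfit: LT cannot follow a pronounced optimum
  p <- invert_traits(305, -3400, 10)
  curve <- make_mmrt_curve(p)
  fm <- fit_mmrt(curve)
  fl <- fit_lloyd_taylor(curve)
  expect_gt(fl$rss, fm$rss)
  cmp <- compare_models(fm, fl)
  expect_identical(cmp$winner, "MMRT")
  expect_equal(cmp$delta, fl$aicc - fm$aicc)

  # refuses fits on different point sets
  other <- fit_lloyd_taylor(make_lt_curve(lt_params(1, 300),
                                          temps_C = seq(6, 46, 2)))
  expect_error(compare_models(fm, other), "different point sets")
})

test_that("delta-method trait errors match the parametric bootstrap", {
  skip_if_not_installed("MASS")
  set.seed(36)
  true <- invert_traits(338, -2400, 18)
  f <- fit_mmrt(make_mmrt_curve(true, sdlog = 0.15))
  draws <- MASS::mvrnorm(1000, f$coef, f$vcov)
  R <- thermo_constants()$R_gas
  boot <- apply(draws, 1, function(b) {
    if (b[2] >= -R) return(c(NA, NA, NA))
    p <- mmrt_params(b[1], b[2], b[3])
    c(kelvin_to_celsius(t_opt(p)), kelvin_to_celsius(t_inf(p)), r25(p))
  })
  for (i in seq_along(c("t_opt_C", "t_inf_C", "r25"))) {
    tr <- c("t_opt_C", "t_inf_C", "r25")[i]
    expect_equal(trait_se_delta(f, tr), sd(boot[i, ], na.rm = TRUE),
                 tolerance = 0.15)
  }

  # zero parameter covariance propagates to zero trait error
  f0 <- f
  f0$vcov <- matrix(0, 3, 3)
  expect_equal(trait_se_delta(f0, "t_opt_C"), 0)

  # T_opt ignores dS0, so its error is blind to the dS0 variance
  f1 <- f
  f1$vcov[3, 3] <- f$vcov[3, 3] * 100
  expect_equal(trait_se_delta(f1, "t_opt_C"), trait_se_delta(f, "t_opt_C"))
})

test_that("Q10 envelopes summarise replicate fits", {
  set.seed(37)
  p <- invert_traits(335, -2000, 12)
  fits <- lapply(1:6, function(i) {
    fit_mmrt(make_mmrt_curve(p, sdlog = 0.1), sample_id = paste0("s", i))
  })
  env <- q10_envelope(fits, groups = rep("g", 6), T_grid_C = 5:40)
  # envelope mean is the arithmetic mean of per-replicate Q10
  q_manual <- rowMeans(vapply(fits, function(f) {
    q10_mmrt(f$params, (5:40) + 273.15)
  }, numeric(36)))
  expect_equal(env$q10_mean, q_manual)
  expect_true(all(diff(env$q10_mean) < 0))
  expect_equal(unique(env$n), 6)

  # identical replicates give a zero-width envelope
  same <- list(fits[[1]], fits[[1]], fits[[1]])
  env0 <- q10_envelope(same, rep("g", 3))
  expect_equal(env0$q10_se, rep(0, nrow(env0)))

  expect_error(q10_envelope(fits[1], "g"), "at least 2")
})
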