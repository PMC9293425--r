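cc <- thermo_constants()

test_that("MMRT log rate matches hand-computed values and structure", {
  # zero parameters: pure transition-state prefactor ln(kB*T/h)
  p0 <- mmrt_params(0, 0, 0)
  expect_equal(mmrt_log_rate(p0, 298.15), log(cc$k_B * 298.15 / cc$h_planck))
  expect_equal(mmrt_log_rate(p0, 298.15), 29.458, tolerance = 1e-4)

  # at T = T0 the heat-capacity terms vanish for any dCp
  for (dcp in c(-3000, -500, 0, 200)) {
    p <- mmrt_params(50e3, dcp, 30)
    expect_equal(mmrt_log_rate(p, cc$T0),
                 log(cc$k_B * cc$T0 / cc$h_planck) -
                   50e3 / (cc$R_gas * cc$T0) + 30 / cc$R_gas)
  }

  # linear in (dH0, dCp, dS0) at fixed temperature
  set.seed(1)
  temp <- 310
  a <- c(6e4, -2e3, 20)
  b <- c(1e4, 5e2, -7)
  lr <- function(v) mmrt_log_rate(mmrt_params(v[1], v[2], v[3]), temp)
  expect_equal(lr(a + b), lr(a) + lr(b) - lr(c(0, 0, 0)))

  expect_error(mmrt_log_rate(p0, -5), "positive")
})

test_that("temperature optimum closed form matches brute-force argmax", {
  p <- mmrt_params(73400, -1400, 27.72)
  expect_equal(t_opt(p), 352.7, tolerance = 1e-4)
  expect_equal(kelvin_to_celsius(t_opt(p)), 79.5, tolerance = 1e-3)

  # dH0 = -T0*R forces T_opt = T0 for any valid dCp
  for (dcp in c(-3000, -1000, -100)) {
    expect_equal(t_opt(mmrt_params(-cc$T0 * cc$R_gas, dcp, 0)), cc$T0)
  }

  set.seed(42)
  for (i in 1:50) {
    p <- random_mmrt_params()
    topt <- t_opt(p)
    coarse <- seq(250, 500, by = 0.5)
    peak <- coarse[which.max(mmrt_log_rate(p, coarse))]
    fine <- seq(peak - 1, peak + 1, by = 0.001)
    expect_lt(abs(fine[which.max(mmrt_log_rate(p, fine))] - topt), 0.01)
  }

  expect_error(t_opt(mmrt_params(5e4, -5, 0)), "optimum")
})

test_that("inflection temperature matches argmax of dR/dT and lies below T_opt", {
  p <- mmrt_params(73400, -1400, 27.72)
  expect_equal(t_inf(p), 325.5, tolerance = 1e-4)
  expect_lt(t_inf(p), t_opt(p))

  set.seed(43)
  for (i in 1:50) {
    p <- random_mmrt_params()
    tinf <- t_inf(p)
    expect_lt(tinf, t_opt(p))
    # numerical argmax of dR/dT by central differences
    h <- 0.01
    grid <- seq(250, t_opt(p), by = 0.05)
    drdt <- (exp(mmrt_log_rate(p, grid + h)) -
               exp(mmrt_log_rate(p, grid - h))) / (2 * h)
    peak <- grid[which.max(drdt)]
    fine <- seq(peak - 0.2, peak + 0.2, by = 0.001)
    drdt_f <- (exp(mmrt_log_rate(p, fine + h)) -
                 exp(mmrt_log_rate(p, fine - h))) / (2 * h)
    expect_lt(abs(fine[which.max(drdt_f)] - tinf), 0.05)
  }

  expect_error(t_inf(mmrt_params(5e4, 1, 0)), "dCp")
})

test_that("R25 equals the rate curve at the reference temperature", {
  # dG0 = 0 gives the bare prefactor kB*T0/h
  p <- mmrt_params(dH0 = cc$T0 * 10, dCp = -2000, dS0 = 10)
  expect_equal(r25(p), cc$k_B * cc$T0 / cc$h_planck)
  expect_equal(r25(p), 6.212e12, tolerance = 1e-4)

  p2 <- mmrt_params(73400, -1400, 27.72)
  expect_equal(dG0(p2), 73400 - 298.15 * 27.72)
  expect_equal(r25(p2), 24.1, tolerance = 0.01)

  set.seed(44)
  for (i in 1:20) {
    p <- random_mmrt_params()
    expect_equal(r25(p), exp(mmrt_log_rate(p, cc$T0)))
  }
})

test_that("Q10 from MMRT matches hand arithmetic and the exact ratio", {
  # dH0 = 5*dCp zeroes the numerator at T0
  expect_equal(q10_mmrt(mmrt_params(-5000, -1000, 0), cc$T0), 1)

  p <- mmrt_params(73400, -1400, 27.72)
  expect_equal(q10_mmrt(p, 298.15),
               exp(10 * (73400 + 5 * 1400) / (8.314 * 298.15^2)))
  expect_equal(q10_mmrt(p, 298.15), 2.97, tolerance = 1e-3)

  # printed form stays within 15% of the centred exact 10 K ratio
  Ts <- seq(283, 313, by = 1)
  centred <- exp(mmrt_log_rate(p, Ts + 5) - mmrt_log_rate(p, Ts - 5))
  expect_true(all(abs(q10_mmrt(p, Ts) / centred - 1) < 0.15))

  # exact forward ratio is its own definition
  expect_equal(q10_exact(p, 290),
               exp(mmrt_log_rate(p, 300) - mmrt_log_rate(p, 290)))

  # q10_exact monotone decreasing over field-like parameter sets
  set.seed(45)
  for (i in 1:20) {
    p <- random_mmrt_params()
    q <- q10_exact(p, seq(278, 318, by = 2))
    expect_true(all(diff(q) < 0))
  }
})

test_that("Lloyd & Taylor log rate and Q10 behave as constructed", {
  p <- lt_params(lnR10 = 0.7, E0 = 308.56)
  # R10 is exactly the 10 degC rate
  expect_equal(lt_log_rate(p, 283.15), 0.7)
  expect_equal(lt_log_rate(lt_params(0, 308.56), 298.15),
               308.56 * (1 / 56.02 - 1 / 71.02))
  expect_equal(lt_log_rate(lt_params(0, 308.56), 298.15), 1.163,
               tolerance = 1e-3)
  # E0 = 0 gives a flat curve
  expect_equal(lt_log_rate(lt_params(2, 0), seq(280, 320, 10)), rep(2, 5))
  expect_error(lt_log_rate(p, 220), "offset")

  expect_equal(q10_lt(0, c(280, 300, 320)), rep(1, 3))
  expect_equal(q10_lt(308.56, 283.15), exp(3085.6 / 56.02^2))
  expect_equal(q10_lt(308.56, 283.15), 2.67, tolerance = 5e-3)
  q <- q10_lt(500, seq(280, 320, by = 5))
  expect_true(all(diff(q) < 0))
})

test_that("relative sensitivity is the analytic log-rate derivative", {
  p <- mmrt_params(73400, -1400, 27.72)
  expect_equal(relative_sensitivity(p, 288.15),
               1 / 288.15 + (73400 - 1400 * (288.15 - 298.15)) /
                 (8.314 * 288.15^2))
  expect_equal(relative_sensitivity(p, 288.15), 0.1301, tolerance = 1e-3)

  # zero exactly at the optimum
  expect_lt(abs(relative_sensitivity(p, t_opt(p))), 1e-10)

  # matches central differences of the log rate
  set.seed(46)
  for (i in 1:20) {
    p <- random_mmrt_params()
    Ts <- runif(5, 270, 330)
    h <- 1e-4
    num <- (mmrt_log_rate(p, Ts + h) - mmrt_log_rate(p, Ts - h)) / (2 * h)
    expect_equal(relative_sensitivity(p, Ts), num, tolerance = 1e-6)
  }
})

test_that("trait inversion round-trips T_opt, dCp and R25", {
  p <- invert_traits(T_opt = 352.7, dCp = -1400, R25 = 24.1)
  expect_equal(p$dH0, 73400, tolerance = 1e-3)
  expect_equal(p$dS0, 27.7, tolerance = 0.01)

  # T_opt = T0 forces dH0 = -T0*R whatever dCp
  for (dcp in c(-3000, -1000)) {
    expect_equal(invert_traits(cc$T0, dcp, 5)$dH0, -cc$T0 * cc$R_gas)
  }

  set.seed(47)
  for (i in 1:200) {
    topt <- runif(1, 300, 400)
    dcp <- runif(1, -3400, -100)
    r <- exp(runif(1, -2, 5))
    p <- invert_traits(topt, dcp, r)
    expect_equal(t_opt(p), topt, tolerance = 1e-9)
    expect_equal(r25(p), r, tolerance = 1e-9)
    expect_identical(p$dCp, dcp)
  }

  expect_error(invert_traits(300, -5, 10), "dCp")
  expect_error(invert_traits(300, -2000, -1), "R25")
})

test_that("constants are validated and configurable", {
  expect_error(thermo_constants(R_gas = -1), "positive")
  expect_error(thermo_constants(T0 = 200), "zero-rate")
  alt <- thermo_constants(T0 = 293.15)
  p <- mmrt_params(5e4, -2e3, 20)
  # reference temperature shifts where the dCp terms vanish
  expect_equal(mmrt_log_rate(p, 293.15, alt),
               log(alt$k_B * 293.15 / alt$h_planck) -
                 5e4 / (alt$R_gas * 293.15) + 20 / alt$R_gas)
})
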