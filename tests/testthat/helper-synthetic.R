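# Shared fixtures: small curves generated in code.

default_temps <- seq(4, 46, by = 2)

# one sample's rate curve from known MMRT parameters (+ lognormal noise)
make_mmrt_curve <- function(params, temps_C = default_temps, sdlog = 0,
                            constants = thermo_constants()) {
  lr <- mmrt_log_rate(params, celsius_to_kelvin_test(temps_C), constants)
  rate <- exp(lr + stats::rnorm(length(temps_C), 0, sdlog))
  data.frame(temperature_C = temps_C, rate_umol_g_min = rate)
}

make_lt_curve <- function(params, temps_C = default_temps, sdlog = 0,
                          constants = thermo_constants()) {
  lr <- lt_log_rate(params, celsius_to_kelvin_test(temps_C), constants)
  rate <- exp(lr + stats::rnorm(length(temps_C), 0, sdlog))
  data.frame(temperature_C = temps_C, rate_umol_g_min = rate)
}

celsius_to_kelvin_test <- function(x) x + 273.15

# random MMRT parameter set in the field-plausible range
random_mmrt_params <- function() {
  mmrt_params(dH0 = stats::runif(1, 38e3, 78e3),
              dCp = stats::runif(1, -3.4e3, -1.1e3),
              dS0 = stats::runif(1, -50, 80))
}

# noise-free generator settings for exactness tests
noise_free_env <- function() {
  environment_model(met_transect_sd = 0, met_sd = 0, ph_sd = 0,
                    c_sdlog = 0, cn_sd = 0)
}

noise_free_traits <- function() {
  trait_model(topt_sd = 0, r25_sdlog = 0, rate_sdlog = 0)
}
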