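Package: thermoresp
Title: Temperature Response of Soil Microbial Respiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the temperature response of soil
    heterotrophic respiration measured in closed-vial headspace
    incubations. Converts headspace CO2 readings to respiration rates,
    fits macromolecular rate theory (MMRT) and Lloyd & Taylor models to
    per-sample temperature-response curves, derives thermal traits
    (temperature optimum, inflection point, reference-temperature rate)
    with delta-method standard errors, compares models by corrected AIC,
    and provides treatment-level statistics (factorial ANOVA, backwards
    stepwise regression, random-intercept model comparison). Includes a
    synthetic-study generator emulating a factorial geothermal-gradient
    design so the full pipeline can be exercised and validated by
    parameter recovery without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    minpack.lm,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
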