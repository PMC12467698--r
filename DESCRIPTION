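Package: irritrace
Title: Capacitive Skin-Irritation Assays on Artificial Stratum Corneum Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of capacitive barrier-disruption assays on
    lanolin-based artificial stratum corneum sensors. Provides an equivalent-circuit
    forward model of the sensor (series dielectric stack, air and electrolyte contact
    paths, leakage resistance), a synthetic trace generator reproducing the instrument's
    noise, temperature drift, exposure protocol and batch variability, a signal pipeline
    extracting baseline, air-subtracted capacitance change and windowed or maximum-rate
    dC/dt slopes, a logarithmic spacer-thickness calibration with inverse prediction,
    and GHS-style irritant classification with Bonferroni-corrected group statistics
    and reproducibility coefficients of variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
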