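Package: edcrowd
Title: Stochastic Population Modelling of Emergency-Department Crowding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models hospital emergency-department (ED) occupancy as a
    stochastic birth-death population process with time-varying arrival
    flux and exit rate, subject to demographic (individual-level) and
    systematic (environment-level) noise. Provides mean-field and
    Langevin forward simulators plus an exact event-driven birth-death
    oracle, a synthetic minute-resolution visit-log generator with a
    calibrated weekly arrival profile, crowding metrics (hourly fluxes,
    momentary occupancy, patient hours, relative shift crowding,
    cohort survival), two-stage parameter estimation (mean-field exit
    rates per day group, then grid maximum likelihood for the two noise
    magnitudes with Gaussian uncertainties), and overcrowding analyses:
    tail probabilities at severe/dangerous thresholds and parameter
    elasticity of overcrowding to arrival flux, length of stay and
    systematic noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
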