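Package: canopyflux
Title: Open-Chamber Canopy Gas-Exchange Flux Processing and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for multiplexed open-chamber canopy gas-exchange
    systems: conversion of analyzer streams to CO2 and H2O fluxes with dilution
    correction, a first-order chamber mass-balance model with dead-time and
    residence-time corrections, steady-state estimation from unsteady transients by
    nonlinear fitting, partial-derivative error propagation, reference-flux
    calibration protocols (CO2 scrubbing and injection ramps), daily solar and
    fluctuating-light PPFD generators, and a seeded virtual multi-chamber facility
    simulator that emits logger files with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    minpack.lm,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
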