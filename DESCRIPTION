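Package: chronicost
Title: Illness-Death Model Projection of Chronic Disease Prevalence and
    Direct Medical Costs
Version: 0.1.0
Authors@R: person("chronicost", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Projects age- and sex-specific prevalence of diagnosed type 1
    and type 2 diabetes by integrating the illness-death model partial
    differential equation along age-time characteristics, and couples the
    projected prevalence to an excess-cost model of direct medical
    expenditures (per capita costs, total and excess costs, cost ratios,
    population attributable costs, national extrapolation) under
    deterministic scenario analysis for Germany 2010-2040. Includes a
    synthetic-data generator emulating the statistical structure of
    aggregated statutory-health-insurance claims and official demographic
    projections, a cohort-component population generator, interpolation
    utilities for grouped age data, a stochastic microsimulation oracle
    for validating the deterministic solver, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
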