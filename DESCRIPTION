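Package: phenrisk
Title: Temperature-Driven Insect Phenology Models and Pest Risk Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building temperature-driven phenology models for
    insect pests from stage-specific life-table data, and for turning them
    into spatial risk indices. Fits the thermal response functions commonly
    used for tephritid fruit flies (Briere-1 development rate, exponential-
    quadratic immature mortality, exponential and Stinner adult senescence,
    polynomial-exponential and Gaussian lifetime fecundity, logistic, gamma
    and cubic-exponential cumulative oviposition, logit development-time
    distributions with a common slope), selects among them by AIC and R2,
    simulates stochastic cohorts by rate summation and cohort updating under
    constant or fluctuating temperatures, estimates Euler-Lotka life-table
    parameters (rm, R0, GRR, generation time, finite rate of increase,
    doubling time), and computes establishment (ERI), generation (GI) and
    activity (AI) risk indices over annual temperature series and gridded
    climatologies with ESRI ASCII grid input/output. A synthetic-data
    generator reproduces the design of constant-temperature rearing studies
    (seven temperatures, replicated cohorts, paired adults) so the whole
    pipeline is testable without access to raw rearing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
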