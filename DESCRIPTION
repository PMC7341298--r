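Package: flockgrowth
Title: Gompertz Growth-Curve Analysis and Simulation for Slow-Growing
    Chicken Flocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-bird Gompertz growth-curve fitting for longitudinal
    body-weight records in two parameterizations (the classical
    asymptote/shape/rate form and the lag-time form with the absolute
    growth rate at the inflection point), with closed-form conversions
    between them and derived maturity traits (inflection age and weight,
    maximum growth rate, predicted slaughter weight, degree of maturity).
    Includes group-level analysis of variance with an allele-sharing
    relationship matrix as a random effect, backward elimination,
    Waller-Duncan k-ratio letter groupings and sexual-dimorphism
    statistics; minisatellite indel allele calling, a Hardy-Weinberg
    randomization test, Weir-Cockerham Fst and per-age genotype
    association scans; and a seed-deterministic synthetic-flock generator
    with known ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
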