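Package: esrsim
Title: Feeding-Cycle Population Genetics of Evolved Spatial Repellents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic two-locus, bi-allelic population-genetics model of
    malaria-vector evolution under combined spatial-repellent and insecticide
    interventions. Tracks insecticide-resistance and deflection alleles over
    gonotrophic feeding cycles in a cohort-structured adult female population
    with delayed juvenile recruitment, Plasmodium acquisition and incubation,
    and an infectious-bite output proportional to the entomological
    inoculation rate. Provides the analytic offspring-fitness equations and
    allele-spread conditions with a brute-force oracle, named scenario
    fixtures, insecticide-swap ("ratchet") experiments, survival-combination
    grid scans, cost-of-resistance scans, and relative infectious-bite
    comparisons, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
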