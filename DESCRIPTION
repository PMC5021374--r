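Package: ringstoich
Title: Ring Stoichiometry Inference from Subunit-Poisoning Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inferring the subunit stoichiometry of oligomeric ring
    ATPases from mutant-doping (subunit poisoning) titration assays. Implements
    closed-form binomial blocking models for rings assembled from mixed
    wild-type/mutant subunit pools, including an arginine-finger-constrained
    dimer-seeded assembly mode; Poisson maximum-likelihood fitting of plaque-count
    titration data over an integer (z, K) grid with AIC model selection and
    bootstrap confidence intervals; rate-zonal gradient analysis (log-mass
    calibration from marker proteins, peak detection, oligomer-order assignment);
    a stochastic ring-assembly oracle and a qualitative sequential-translocation
    state machine with mutant-induced stalling; and seeded synthetic-data
    generators for both assay types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
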