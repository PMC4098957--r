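Package: igesim
Title: Stochastic Simulation of BLUP Selection for Socially Affected Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation of a closed aquaculture breeding nucleus
    selecting on socially affected traits, i.e. traits with indirect genetic
    effects (IGE). Provides derivation of direct/indirect (co)variance
    components from scenario parameters, pedigree machinery (Meuwissen-Luo
    inbreeding coefficients, Henderson's inverse numerator relationship
    matrix, rate-of-inbreeding statistic), an exact sparse BLUP evaluation of
    the direct-indirect animal model with group structure, and an experiment
    driver that runs replicated truncation-selection programs and summarises
    rates of inbreeding and sib correlations of estimated total breeding
    values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
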