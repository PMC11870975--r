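Package: btksim
Title: Ibrutinib-BTK Covalent Binding Model and Virtual Trial Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of Bruton's tyrosine kinase (BTK) occupancy
    under once-daily oral ibrutinib. Couples a two-compartment population
    pharmacokinetic model with sequential zero/first-order absorption to a
    covalent (kinact/KI) target binding model with free-BTK turnover. Provides
    virtual-population trial simulation with lognormal between-subject
    variability, dose-response sweeps with parameter-uncertainty bands, ED90
    estimation from sigmoid Emax fits, sequential dose-reduction regimens, and
    evaluation against pooled observed occupancy proportions with exact
    binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
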