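Package: tniche
Title: Niche Competition Model of Mature T-Cell Homeostasis and
    Oncogenic Transformation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic resource-competition model of mature T-cell
    homeostasis in which TCR-defined clones compete for prohomeostatic
    stimuli supplied by self-peptide-MHC niches. Each clone is split into a
    healthy and a preleukemic (oncogene-transduced) species; species acquire
    niche resources in proportion to affinity-weighted abundance and grow
    logistically towards a dynamic carrying capacity. The package provides
    the model equations, in-silico transplantation initial conditions, an
    adaptive ODE integrator with a steady-state stopping rule and
    perturbation (cell-kill) events, an exhaustive fold-change parameter
    screen over the preleukemic species' specific affinity, unspecific
    affinity and resource-utilization efficiency with classification of
    monoclonal versus polyclonal outcomes, and post-processing of the
    consistent parameter region (counts, marginals, octants, u-v band).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    optparse,
    parallel,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
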