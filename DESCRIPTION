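Package: gelbead
Title: Swelling and Drug-Release Modelling for Porous Hydrogel Beads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modelling of solvent uptake and drug release from highly
    porous polysaccharide beads (gellan gum, with or without laponite clay).
    Implements a moving-boundary swelling model with a diffuse glassy-rubbery
    interface (concentration-dependent solvent diffusivity), coupled Fickian and
    two-phase (bound/free) drug-transport solvers under finite-reservoir dissolution
    protocols with withdrawal sampling and sequential gastric/intestinal media,
    nonlinear parameter estimation on swelling and differential release data, and a
    synthetic-data generator reproducing the statistical structure of triplicate
    bench experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    patchwork,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
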