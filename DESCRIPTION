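Package: memmkin
Title: Multi-Ensemble Markov Models for Ion Translocation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of thermodynamics and kinetics of ion translocation
    through a membrane receptor from mixed biased (umbrella sampling) and
    unbiased trajectory ensembles. Provides a Brownian-dynamics generator on
    analytically known two-dimensional free-energy landscapes, time-lagged
    independent component analysis (tICA) featurization, WHAM density
    reweighting with OpenDX export, microstate discretization, discrete TRAM
    estimation of multi-ensemble Markov models, PCCA+ coarse-graining with
    Hummer-Szabo projection, mean first passage times, a constant-pH
    protonation-mixing kinetic model, concentration-dependent binding and
    egress kinetics via Smoluchowski bulk coupling, and a two-state receptor
    model of allosteric modulation of agonist binding by sodium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
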