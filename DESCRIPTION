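Package: chronodiv
Title: Historical Biogeography, Elevational Trait Evolution and
    Time-Dependent Diversification on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenetics toolkit for Neotropical radiations on
    ultrametric chronograms: a time-stratified Dispersal-Extinction-Cladogenesis
    (DEC) model with per-epoch dispersal multiplier matrices, maximum-likelihood
    estimation of dispersal and extirpation rates, marginal ancestral range
    reconstruction and biogeographic event counting; joint maximum-likelihood
    estimation of Pagel's lambda and delta branch-scaling parameters for
    continuous elevational traits with likelihood-ratio tests and rescaled
    ancestral reconstruction; six time-dependent birth-death diversification
    models with exponential rate functions, AIC model selection,
    rate-through-time curves and a stepwise clade rate-shift scan with a
    posterior-frequency significance rule; and seeded simulators of birth-death
    chronograms, Brownian-motion traits and DEC range histories so that every
    stage can be exercised and calibrated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
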