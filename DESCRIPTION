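Package: hybridferm
Title: Hybrid Mechanistic-LSTM Modeling of Mixed-Sugar Yeast Batch Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling aerated batch fermentation of Saccharomyces
    cerevisiae on mixed sugars (sucrose, glucose, fructose) with urea as the
    nitrogen source. Provides a six-state Monod-type kinetic model with smooth
    catabolite-repression gating, grey wolf global parameter calibration with
    iterative bound refinement, practical identifiability analysis
    (significance, correlation, sensitivity screening with sequential
    parameter fixing), Monte Carlo uncertainty bands, and a look-back-window
    LSTM residual learner whose predictions are blended with the mechanistic
    trajectory through a weighted sum. Includes a synthetic-experiment
    generator with polynomial densification for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
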