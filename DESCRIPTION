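Package: thermoplaid
Title: Virtual Thermal-Plaid Behavior Simulation and Sensorimotor Encoding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates closed-loop "thermal plaid" navigation experiments in
    which virtual larval zebrafish swim in discrete bouts through a doubly
    periodic temperature field, together with yoked open-loop replay controls.
    Provides swim-bout detection from tail-angle traces, a small convolutional
    network encoder of swim-initiation probability trained with binary
    cross-entropy, receptive-field extraction by differentiating the trained
    network, transformation of receptive fields into bout-frequency modulation,
    linear decoding of feedback condition from simulated mixed-selectivity
    neuron activity, and fish-level bootstrap statistics for clustered
    behavioral data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    glmnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
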