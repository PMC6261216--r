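Package: fermgpc
Title: Generalized Predictive Control of Fermentation Biomass with PSO-Tuned
    LS-SVM Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Data-driven modelling and receding-horizon control of bacteria
    concentration in fed-batch fermentation. Identifies a nonlinear
    autoregressive (NARX) model of biomass concentration from substrate
    feed-rate records by least-squares support vector machine (LS-SVM)
    regression with a Gaussian kernel, tunes the regularization and kernel
    width by particle swarm optimization against a held-out calibration set,
    linearizes the fitted model at each operating point by a first-order
    Taylor expansion, and closes the loop with a generalized predictive
    controller (GPC) on the CARIMA form under feed-rate amplitude and
    increment constraints. Includes a Monod-kinetics fed-batch simulator for
    generating realistic training batches, tracking-performance metrics, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
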