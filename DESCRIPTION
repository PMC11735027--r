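Package: switchddm
Title: Drift-Diffusion Modelling and Ensemble Analysis of Striatal Interval Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-parameter drift-diffusion model of switch
    response times in a mouse interval-timing task, fits gamma distributions
    to response-time samples and selects drift/noise parameters by grid
    search against behavioral targets. Provides peri-event time histogram
    construction, ensemble PCA with a random-timestamp baseline,
    trial-by-trial GLM ramp slopes, optogenetic-tagging classification,
    naive-Bayes temporal decoding with leave-one-out cross-validation, and
    an exponential-kernel plus logistic ensemble readout that predicts
    trial-by-trial switch times. A synthetic-data module generates
    behavioral event logs and spike-train ensembles with the statistical
    structure the analyses assume, so the full pipeline is testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    MASS,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
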