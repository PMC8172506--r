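Package: irmpro
Title: Item Response Modelling of Daily Patient-Reported Outcome Diaries
Version: 0.1.0
Authors@R: person("IRM", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Item-based pharmacometric analysis of daily 14-item COPD
    symptom diaries (EXACT / E-RS:COPD).  Implements a graded response
    model for the item characteristic functions, latent disease-status
    trajectories with inter-individual variability, a continuous-time
    Markov layer for day-to-day correlation, two-step maximum-likelihood
    estimation, simulation-based model diagnostics (visual predictive
    checks), propagation of parameter uncertainty into end-of-trial score
    differences, and the decision-confidence layer (sample-size ratio,
    go/stop probability tables under a mixture prior, PPV/NPV, power
    curves and ROC/AUC) used to compare the item-based analysis with a
    summary-score mixed-model analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
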