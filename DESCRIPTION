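Package: likelyresponder
Title: Likely-Responder Causal Reanalysis of Two-Arm Randomized Trials
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the likely-responder paradigm for re-analysing a
    two-arm randomized clinical trial with a heterogeneous treatment effect.
    A regression random forest fit on the active arm predicts each subject's
    counterfactual response to active treatment from baseline features;
    subjects whose predicted improvement clears a clinically motivated
    threshold are classified as likely responders.  Treatment superiority is
    then tested within contiguous quantile strata of the prognostic score by
    stratified linear regression, with closed testing to control the
    family-wise error rate, plus baseline and end-of-study group
    comparisons and a perturbation-based per-feature risk-difference
    analysis.  A synthetic-trial generator with oracle access to each
    subject's true treatment effect supports calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
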