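Package: careseq
Title: Childcare Sequence Typologies and Mental Health Inequalities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how longitudinal patterns of early-years
    childcare mediate socioeconomic inequalities in child mental health.
    Provides a calibrated synthetic-cohort generator (maternal education,
    confounders, seven-state childcare sequences over four sweeps, a binary
    raised Total Difficulties outcome, survey weights and attrition),
    optimal-matching dissimilarities with weighted Ward clustering into
    childcare typologies with bootstrap stability checks, survey-weighted
    multinomial and modified-Poisson (risk ratio) inequality models with
    sandwich variances, and marginal structural logistic models with
    stabilized inverse-probability weights for average treatment effects
    and controlled direct effects under hypothetical universal-childcare
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    sandwich,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
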