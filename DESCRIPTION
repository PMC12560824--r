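Package: proflux
Title: Predicting Metabolic Reaction Rates from Proteome Abundances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies covariation between enzyme abundances and in vivo
    reaction rates across steady-state (chemostat) growth conditions, and
    predicts individual reaction rates from focal-enzyme, within-pathway, and
    proteome-wide abundances using penalized linear regression (ridge/LASSO)
    with nested cross-validation and a cross-validated R-squared statistic.
    Includes a mechanistic synthetic-data generator (first-order branched
    pathway kinetics at steady state embedded in a factorial media-by-dilution
    chemostat design) so that every stage of the analysis can be verified
    against known ground truth, plus readers and writers for the tab-separated
    and GMT formats the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    Rcpp,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
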