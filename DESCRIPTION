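Package: aetrend
Title: Incidence Trends and Moderated AE Liability-Threshold Heritability
    in Sibling Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates registry-style cohorts of full-sibling families with a
    rare, threshold-determined childhood disease and analyses them the way
    nationwide register studies of childhood-onset type 1 diabetes are
    analysed: Kaplan-Meier cumulative incidence and Cox birth-cohort hazard
    ratios with mother-clustered robust errors, maximum-likelihood AE
    liability-threshold models for full-sibling pairs with birth-year
    moderation of the genetic and non-shared-environment path coefficients,
    family-bootstrap confidence intervals, a counterfactual
    heritability-attenuation calculation, full-cohort and sibling-stratified
    environmental risk-factor associations, and a survival-setting causal
    mediation decomposition of the rise in cumulative incidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
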