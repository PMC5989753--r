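Package: ebmstage
Title: Event-Based Modelling and Staging of Cognitive Decline
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits event-based models (EBM) of disease progression to
    cross-sectional cognitive and informant-rated biomarker batteries.
    Per-biomarker abnormality is modelled with semisupervised two-component
    kernel density mixture models initialised from age-defined control and
    disease groups; the maximum-likelihood ordering of decline events is
    found by greedy ascent plus Markov chain Monte Carlo over permutations,
    with bootstrap positional variance diagrams quantifying uncertainty.
    Participants are assigned maximum-likelihood disease stages and stage
    distributions are compared between clinical groups with Mann-Whitney U
    tests. Includes a synthetic cohort generator with a known ground-truth
    event sequence, floor and ceiling truncation, intellectual-disability
    baseline offsets, item missingness and task non-engagement, so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
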