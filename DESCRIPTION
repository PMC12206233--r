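Package: brainNAT
Title: Network Attack Tolerance of Functional Brain Connectomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the resilience of functional brain
    networks to targeted node attack. Builds Fisher-z ROI-to-ROI
    connectivity matrices from resting-state time series, applies
    proportional thresholding and binarization across a density sweep,
    simulates degree-targeted node removal, and summarizes the decay of
    global efficiency as a normalized network attack tolerance (NAT)
    score per participant, network and density. Includes beta-response
    mixed models relating NAT to dopaminergic integrity and reserve
    proxies, linear moderation models with Johnson-Neyman significance
    regions, lifetime physical-activity (weekly energy expenditure)
    scoring, composite motor/cognitive performance scores referenced to
    healthy controls, and a synthetic-cohort generator that emulates the
    statistical structure of an early Parkinson's disease imaging study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    glmmTMB
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
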