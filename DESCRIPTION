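Package: protomark
Title: Protein Marker Discovery in Matched Case-Control Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pre-diagnostic protein biomarker discovery
    in 1:1 matched case-control studies nested within prospective cohorts.
    Provides a synthetic multi-cohort study generator with planted effects,
    NPX-style preprocessing (limit-of-detection substitution, duplicate-assay
    resolution, within-cohort standardization), conditional logistic
    regression on matched sets, effective-number-of-tests and FDR multiplicity
    control, a resampling discovery-replication selection algorithm,
    stratified odds-ratio, heterogeneity and lead-time trend analyses,
    incremental AUC over a baseline risk score, graphical-lasso stability
    networks of residualized proteins, preclinical sojourn-time stage
    back-calculation, and stratified Cox survival models with lead-time
    interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
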