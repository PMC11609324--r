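Package: ernfc
Title: Emotion Regulation Network Connectivity and Family-Nested
    Psychopathology Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline relating parental psychopathology to youth
    resting-state connectivity of four meta-analytic emotion-regulation
    brain networks. Maps peak-sphere or cluster regions of interest onto a
    labelled parcellation volume, reduces subject-level parcel-by-parcel
    Fisher-z connectivity matrices to within- and between-network mean
    features, removes scanner batch effects with a parametric
    empirical-Bayes location/scale (ComBat-type) adjustment, fits
    family-nested linear mixed models with cluster-bootstrap inference and
    Benjamini-Hochberg false-discovery-rate correction, and estimates
    multilevel mediation models that split the mediator-outcome path into
    within- and between-family effects. Ships a synthetic-cohort generator
    (families, sites, skewed sum scores, planted effects) so every stage is
    testable end to end without restricted data.
License: MIT
Encoding: UTF-8
Imports:
    lme4,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
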