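Package: pdacnerve
Title: Quantification of Sympathetic Innervation in Pancreatic Cancer Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of sympathetic nerve remodelling
    in murine pancreatic ductal adenocarcinoma (PDAC). Provides whole-organ
    nerve volumetrics from 3D binary segmentation masks, skeleton-based
    axon/vessel morphometry with a 12-variable contact profile, Z-score /
    PCA / Ward-clustering staging of tissue samples, a hierarchical Bayesian
    Gompertz model for longitudinal log-bioluminescence tumor growth curves
    (fitted by MCMC through JAGS), and Kaplan-Meier / log-rank / hazard-ratio
    survival endpoints including a maximally-selected expression cutpoint.
    A synthetic-data module generates tubular axon/vessel phantoms, growth
    cohorts and survival cohorts with planted ground truth so that every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    rjags,
    coda,
    survival,
    mclust,
    MASS,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
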