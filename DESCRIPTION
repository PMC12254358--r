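Package: twinlink
Title: Bivariate Classical Twin Modelling for Synaesthesia and
    Neurodevelopmental/Psychiatric Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for estimating genetic and environmental
    contributions to the association between self-reported synaesthesia and
    neurodevelopmental/psychiatric symptom scales in twin cohorts. Includes a
    synthetic twin-cohort generator with a known bivariate ACE structure,
    item-level scale scoring with completeness rules, Cronbach's alpha and
    skew-gated transformations, one-twin-per-pair Pearson correlations with
    Pearson-Filon comparisons of dependent correlations, and a full-information
    maximum-likelihood engine for saturated and bivariate Cholesky (correlated
    factors) ACE models with likelihood-ratio model selection, profile-likelihood
    confidence intervals, and decomposition of the phenotypic correlation into
    genetic and environmental shares.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
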