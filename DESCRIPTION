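Package: anchormi
Title: Anchoring-Vignette Adjustment and Measurement-Invariance Analysis
    for Ordinal Rating Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing and repairing the cross-group comparability
    of ordinal rating data with anchoring vignettes. Implements the
    non-parametric vignette rescaling of self-reports (including
    interval-valued rescaled scores under tied or misordered vignette
    ratings), maximum-likelihood estimation of the compound hierarchical
    ordered probit (CHOPIT) with covariate-driven response thresholds and a
    Gauss-Hermite-integrated respondent random effect, and a multi-group
    confirmatory factor analysis engine with mean structure: configural,
    metric and scalar invariance sequences, chi-square/CFI/RMSEA/adjusted-BIC
    decision rules, score-test modification indices, manifest-covariate
    models and composite reliability. A synthetic vignette-survey generator
    with injectable response-category differential item functioning makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
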