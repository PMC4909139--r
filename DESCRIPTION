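Package: stuntineq
Title: Wealth-Related Inequality in Child Stunting Across Repeated National Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify socio-economic inequality in child stunting
    (height-for-age z-score below -2) from household-survey microdata and to
    track how that inequality evolves across repeated national surveys.
    Implements asset-index wealth scoring by principal component analysis with
    weighted quintile assignment, design-based prevalence estimation (sampling
    weights, clustering, stratification) via Taylor linearization, the slope
    index of inequality estimated by logistic regression on weighted fractional
    ranks, the relative concentration index with cluster-jackknife uncertainty,
    simple top/bottom-quintile contrasts, and per-decade trend estimation with
    earliest-versus-latest significance tests. A synthetic-cohort generator
    produces multi-country DHS/MICS-like clustered microdata with known
    ground-truth inequality parameters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
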