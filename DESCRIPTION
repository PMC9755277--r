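Package: mddineq
Title: Socio-Economic Inequality Analysis of Minimum Dietary Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Survey-weighted measurement and decomposition of socio-economic
    inequality in minimum dietary diversity (MDD) among children aged 6-23
    months, following the concentration-index methodology used with
    Demographic and Health Survey (DHS) child-recode data. Provides weighted
    fractional ranks with tie-group midpoints, concentration curves, the
    concentration index by the convenient covariance approach with
    heteroskedasticity- and cluster-robust inference, the regression-based
    (linear probability model) decomposition of the index into per-covariate
    contributions, an asset-based wealth index from weighted principal
    components, an arithmetic verifier for published decomposition tables,
    and a calibrated synthetic DHS-style survey generator with an analytic
    decomposition oracle for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
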