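Package: vitdmr
Title: Nonlinear Mendelian Randomization of Vitamin D Status and Sarcopenia Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the dose-response relationship between serum
    25-hydroxyvitamin D concentration and sarcopenia with instrumental-variable
    methods. Provides a synthetic cohort generator with a configurable true
    causal curve, weighted allele-score instrumentation with allele
    harmonization, observational category models and fractional-polynomial
    dose-response fits, collider-safe residual stratification with per-stratum
    ratio (localized average causal effect) estimates, fractional-polynomial
    nonlinear Mendelian randomization with nonlinearity tests, and
    summary-statistic sensitivity estimators (inverse-variance weighted,
    weighted median, MR-Egger, MR-PRESSO, radial MR) implemented from first
    principles. A config-driven pipeline orchestrates end-to-end runs with
    reproducible seeds and machine-readable outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    metafor,
    withr
Config/testthat/edition: 3
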