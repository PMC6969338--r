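Package: twinmotion
Title: Heritability of MRI Head Motion and Scan Quality in Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies head motion and scan quality in paediatric MRI
    sessions and decomposes their variation into genetic and environmental
    components using the classical twin design. Computes framewise and
    absolute displacement from rigid-body motion parameters, applies
    run-level quality-control rules (maximum-motion, outlier-fraction and
    manual-rating criteria), derives scan quantity and quality phenotypes,
    and fits a maximum-likelihood ACE variance-decomposition model with
    profile-likelihood confidence intervals. A synthetic twin-cohort
    generator with heritable motion propensity, scanner-related distress
    and attrition makes the full pipeline testable end to end without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
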