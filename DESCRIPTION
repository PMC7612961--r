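Package: pspstage
Title: In Vivo Tau-PET Staging of Progressive Supranuclear Palsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify regional 18F-flortaucipir binding with a
    basis-function implementation of the simplified reference tissue model,
    convert regional nondisplaceable binding potentials to covariate-adjusted
    w-scores against a control cohort, derive data-driven regional abnormality
    thresholds by permutation-tested binary recursive partitioning, and assign
    in vivo neuropathology-style stages for progressive supranuclear palsy
    using a cumulative pallidal, frontal/cerebellar, occipital two-step scheme.
    Includes validation statistics (severity ANOVA, Spearman agreement with
    postmortem stage, residualized correlation) and a seeded synthetic-cohort
    generator so the whole pipeline can be exercised end-to-end without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
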