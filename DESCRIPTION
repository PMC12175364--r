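Package: sddsurv
Title: Simulation of Microbiological Surveillance Strategies During
    Selective Digestive Decontamination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing microbiological surveillance strategies
    during Selective Digestive Decontamination (SDD) in the intensive care
    unit by in-silico scenario reduction. Builds culture subsets for
    twice-weekly, once-weekly, and admission-only surveillance scenarios,
    deduplicates isolates into new (species, susceptibility-profile)
    findings, classifies clinical relevance, detects colonisation
    persistence events that would trigger SDD intensification, estimates
    detection rates per 1,000 ICU days with admission-level percentile
    bootstrap confidence intervals, and summarises per-culture laboratory
    costs with median imputation. Includes a calibrated synthetic cohort
    generator so every stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
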