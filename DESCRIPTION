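Package: ddx41curate
Title: Evidence-Based Classification of Germline DDX41 Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curating germline DDX41 variants in myeloid
    malignancy predisposition. Implements a Bayesian multinomial
    likelihood-ratio (OddsPath) model that converts the pattern of somatic
    DDX41 second hits observed in variant carriers into ACMG/AMP PP4
    evidence, an ancestry-matched quasi-case-control engine with
    Haldane-corrected odds ratios for PS4 case enrichment, calibrated
    in-silico score thresholds (REVEL/AlphaMissense with a SpliceAI
    override) for PP3/BP4, and a point-based evidence combiner producing
    five-tier classifications. A synthetic-cohort generator reproduces the
    statistical structure these analyses assume, so the whole pipeline is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
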