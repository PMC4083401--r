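Package: coscore
Title: Clinical Outcome Scoring and Candidate Prioritization for Tumor
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate tumor biomarkers and therapeutic targets
    from transcriptome data. Selects candidates from differential-expression
    result tables (FDR and fold-change thresholds, cellular-compartment and
    ortholog annotation), post-filters chimeric-transcript calls (replicate
    concordance, control subtraction, read-through and homologue-pair
    classification), harmonizes multi-cohort clinical follow-up into
    standardized survival and metastasis records with cohort-level
    test/validation splits, and computes a Clinical Outcome (CO) score per
    feature: expression is dichotomized into UP/DOWN groups by exact
    one-dimensional 2-means, censored exponential survival models are
    compared by likelihood-ratio test, and the observed significance is
    referred to a permutation-plus-subsampling null distribution. A
    synthetic-cohort generator with known ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
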