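Package: mpscolon
Title: Derivation and Application of the mPS_colon Prognostic Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the mPS_colon molecular prognostic score pipeline for
    gastrointestinal tumors: two-filter prognostic-gene selection combining
    negative-binomial differential expression with a DerSimonian-Laird
    random-effects meta-analysis of median-dichotomized Cox hazard ratios;
    binary Gene_Score transformation of expression status against each gene's
    integrated hazard ratio; L1-penalized training on a truncated-survival
    target with weights normalized to a 0-50 score; scoring and four-way risk
    stratification of new cohorts; and Kaplan-Meier, log-rank and Cox
    proportional-hazards validation. Ships the published 16-gene signature as
    a plain-text fixture and a synthetic-data generator so that every pipeline
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
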