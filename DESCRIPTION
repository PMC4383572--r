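Package: estroscreen
Title: Transcriptional and Phenotypic Screening of Candidate Estrogenic Chemicals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-vivo-style screen for classifying candidate estrogenic
    chemicals as non-estrogenic, short-acting, long-acting, or intermediate.
    Extracts coexpression patterns from multi-treatment time-course expression
    data by signal-to-noise and magnitude filtering with correlation-seeded
    pattern discovery, derives 2-hr (estrogenicity) and 24-hr (longevity)
    biomarker transcript panels by a combined ANOVA and PCA approach, scores
    uterotrophic bioassay endpoints (weight, EdU, TUNEL, epithelial cell
    height, Birc1a/Ltf induction) with Tukey or Fisher LSD post-hoc tests, and
    combines transcriptional and phenotypic evidence into a rule-based
    compound classification. Includes a synthetic-study generator so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mclust,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
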