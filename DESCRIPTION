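Package: thtargets
Title: Identification of Thyroid Hormone Direct Response Genes from
    Cycloheximide Blocking Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying direct transcriptional targets of thyroid
    hormone (TH) from a four-condition expression experiment (control, TH,
    cycloheximide (CHX), TH+CHX). Provides a negative-binomial Wald test for
    differential expression with Benjamini-Hochberg correction, classification
    of genes into direct, late and CHX-response classes by CHX resistance,
    scanning of promoter windows for the degenerate DR4 thyroid response
    element (AGGTCANNNNAGGTCA) under a mismatch budget, construction of a
    position-frequency/information-content consensus motif from the hits,
    hypergeometric over-representation analysis, FPKM normalization and
    transcript length statistics, relative qPCR quantification by the
    2^-ddCt method, and a seeded negative-binomial simulator of the full
    experimental design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
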