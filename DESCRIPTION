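Package: promsig
Title: Promoter-Signature Prediction of Tissue-Specific Enhancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains tissue-specific classifiers on transcription-factor
    binding-site features of conserved non-coding elements (CNEs) in the
    promoters of highly versus lowly expressed genes, and applies them
    genome-wide to score distal conserved (and sliding-window) sequences as
    candidate enhancers. Provides position-weight-matrix scanning with exact
    dynamic-programming p-value calibration, class-weighted linear
    support-vector machines with consistent-positive-set double-loop
    cross-validation, sign-preserving weight scaling for motif ranking,
    locus-level enrichment statistics, and a fully seeded synthetic-genome
    generator with planted regulatory truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
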