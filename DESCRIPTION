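Package: combsig
Title: Detecting Combinatorial Responses to Paired Signals in Factorial
    Expression Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether genes respond to a combination of two signalling
    molecules differently from the sum of their individual effects, as in
    two-signal quorum-sensing transcriptome experiments. Implements a
    four-treatment factorial pipeline: quantile normalization, empirical-Bayes
    moderated t-statistics to define the regulated gene set, per-gene
    standardization, a permutation test on the squared deviance from
    additivity (with pooled, per-gene and exact enumeration null modes),
    Holm correction, directional classification, and an exact binomial
    enrichment test with Clopper-Pearson intervals. Includes a synthetic
    factorial-expression generator with known additive and synergistic genes
    so every stage can be verified without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
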