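Package: tnfit
Title: Fitness Estimation and Gene-Level Inference for Serial-Passage
    Transposon Insertion Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Tn-seq forward genetic screens grown over
    serial passages. Computes per-insertion fitness from insertion-frequency
    change and viable-cell population expansion, treatment-to-control relative
    fitness, gene-level means with confidence intervals and
    Benjamini-Hochberg-adjusted one-sample t-tests, candidate selection and
    cross-screen overlaps, quality-control diagnostics, and downstream
    spectral-count differential abundance and cell-length proportion
    statistics. Includes a synthetic screen generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
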