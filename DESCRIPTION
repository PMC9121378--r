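Package: tcrmil
Title: Multi-Instance Deep Learning for Cancer Detection from T Cell
    Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores T-cell-receptor CDR3 beta-chain sequences for cancer
    association with a convolutional filter bank whose filter widths follow
    the observed sizes of contiguous peptide-contacting CDR3 residue
    regions, and aggregates the per-TCR scores into a repertoire-level
    cancer prediction with a learned linear multi-instance classifier.
    Includes repertoire input/output with quality filtering and shared
    reference-set removal, published amino-acid biochemical encodings and a
    PCA pipeline for deriving new ones, end-to-end gradient training with
    dropout and early stopping, ROC/Youden evaluation with plain and nested
    cross-validation, and a synthetic repertoire generator with planted
    variable-length motifs for benchmarking the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
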