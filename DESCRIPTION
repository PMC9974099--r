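Package: cafid
Title: Identification of Cancer-Associated Fibroblasts in Glioblastoma
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for identifying cancer-associated fibroblasts (CAFs)
    in glioblastoma single-cell RNA-seq: quality control and log
    normalization, Gaussian-kernel marker-panel probability scoring with
    negative selection, windowed expression-based copy-number inference to
    exclude chr7-gain/chr10-loss malignant cells, cell-type composition and
    CAF stage scoring, thresholded ligand-receptor crosstalk maps, and
    spatial proximity analysis on cell-type probability fields. Includes a
    negative-binomial synthetic-data generator with planted ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
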