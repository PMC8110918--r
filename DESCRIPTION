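Package: pdacImmune
Title: Marker-Gene Definition and Scoring of Immune Cells in Tumor Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines and uses tumor-specific immune-cell marker genes from bulk
    expression data. Implements a slope-penalizing pairwise-similarity metric
    for candidate marker co-expression, a threshold-based marker selection
    procedure, a gene-set concordance statistic with a permutation null, and
    per-sample cell-type scoring with relative abundance against a CD45+
    reference and between-group Welch t-tests. Ships curated candidate and
    selected marker-gene catalogs for pancreatic ductal adenocarcinoma (PDAC),
    readers for tab/comma-separated expression matrices and NanoString RCC
    files, housekeeping normalization, a detection-threshold filter, and a
    synthetic-data generator with planted co-expression blocks for end-to-end
    testing without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
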