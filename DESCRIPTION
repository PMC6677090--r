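Package: srnapool
Title: Small RNA Tag Processing and Exact Differential Expression for Two
    Pooled Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing small-RNA sequencing experiments in which two
    conditions are each sequenced as a single pooled library. Provides read
    cleaning and tag collapsing, exact-match quantification of mature miRNAs
    against a catalog with tags-per-million normalisation, an exact
    conditional count test (Audic-Claverie family) with Benjamini-Hochberg
    false discovery rate control for calling differentially expressed miRNAs,
    isomiR end-variant classification and seed-region editing detection,
    hypergeometric over-representation analysis, and relative qPCR
    quantification by the 2^-ddCt method. Includes a synthetic-data generator
    with full ground truth so every pipeline stage can be validated without
    access to real sequencing libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
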