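Package: bilinscreen
Title: Analysis of Bi-Lineage Keratin Differentiation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for arrayed shRNA differentiation screens read
    out by two-channel keratin immunofluorescence. Calibrates keratin-5 and
    keratin-8 positivity thresholds on luminal (MCF7-like) and basal
    (MCF10A-like) gating-control wells, classifies single cells into the four
    K5/K8 populations, summarizes wells with a minimum-cell-count quality
    filter, scores shRNA constructs against pooled vector controls by z-score,
    applies a two-independent-construct rule for gene-level hits, and reports
    the screen's background and chance-double-hit frequencies. Downstream
    quantification covers efficiency-corrected (Pfaffl) relative qPCR
    expression, differential-expression filtering with Benjamini-Hochberg
    adjustment, and overlap counting between knockdown signatures. A seeded
    synthetic-screen generator with planted differentiator genes and cytotoxic
    constructs makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
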