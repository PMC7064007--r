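Package: stemnet
Title: Signed Co-Expression Networks for Stem Secondary Cell Wall Regulator Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for identifying candidate regulators of
    secondary cell wall (SCW) deposition from developing-internode RNA-seq
    transcriptomes. Implements low-expression filtering, TMM/log-CPM
    normalization, batch-effect estimation and removal, signed weighted gene
    co-expression network construction with topological overlap and module
    detection, strong-correlation module refinement, intramodular-connectivity
    hub ranking, GO and custom gene-list over-representation tests, two-layer
    top-k bait-gene subnetwork extraction around MYB/NAC transcription factors
    with enrichment-level classification, and Van Soest fiber-fraction
    arithmetic with stage-wise comparisons. Ships a negative-binomial
    synthetic-data generator with planted module structure so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    limma,
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
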