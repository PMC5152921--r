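Package: vdrfun
Title: Functional Profiling and Cluster-Stability Analysis of Vitamin D
    Receptor Orthologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing vitamin D receptor (VDR)
    orthologs and paralogs across species by their functional assay
    profiles. Implements competitive radioligand-binding analysis
    (specific binding, one-site competition IC50 fits, Cheng-Prusoff
    conversion to Ki), dual-luciferase reporter normalization for
    transient transactivation and mammalian two-hybrid assays, assembly
    of coregulator-annotated assay-response matrices, hierarchical
    clustering of receptors by functional profile (Manhattan distance,
    complete linkage), and a bootstrap cluster-recapitulation analysis
    that scores the stability of receptor clusters and ranks nuclear
    receptor coregulators as drivers of the cluster pattern. A
    synthetic-data module generates all inputs with known ground truth
    so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
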