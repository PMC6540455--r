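Package: corsig
Title: Driver-Gene Correlation Signatures for Transcriptome Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers sets of genes whose expression correlates with a
    named driver gene across tumour transcriptomes. Implements the
    probe-level workflow for exon-array data (coherent driver-probe
    selection, correlation screening, median/IQR standardisation,
    probe-to-gene aggregation, gene-level correlation filtering) and its
    gene-level analog for RNA-seq expression matrices, together with
    Ward/Euclidean hierarchical clustering of the resulting signatures,
    a cumulative-proportion transform for cross-platform and
    cross-species comparison of expression cohorts, and a latent-factor
    synthetic-data generator with full ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
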