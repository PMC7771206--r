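Package: epistroma
Title: Linking Chromatin Accessibility to Image-Derived Epithelial Tissue
    Proportion
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative analysis pipeline for matched ATAC-seq and
    histopathology cohorts. Computes the epithelial tissue proportion from
    segmentation label masks, screens chromatin-accessibility peaks for
    Spearman association with the proportion under Benjamini-Hochberg FDR
    control, links significant peaks to candidate target genes via
    strand-aware promoter windows and correlation-based distal links with
    copy-number and promoter-overlap filters, performs hypergeometric
    over-representation analysis of the target genes, and stratifies
    patient prognosis with Kaplan-Meier/log-rank screening and k-means
    risk grouping. Includes a seeded synthetic-data generator that emulates
    every input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
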