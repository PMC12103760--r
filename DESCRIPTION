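Package: ciberscreen
Title: Analysis and Simulation of Barcoded CRISPRi Expression-Reporter Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for CiBER-seq style screens, in which each CRISPRi guide is
    linked to expressed RNA barcodes whose sequencing counts report a
    transcriptional phenotype. Provides anchored, mismatch-tolerant barcode
    counting from FASTQ; the published filtering and guide-level aggregation
    rules; a paired moderated-t analysis of reporter/normalizer count
    log-ratios with empirical-Bayes variance shrinkage and
    Benjamini-Hochberg FDR; matched-promoter RNA-to-RNA normalization
    alongside conventional RNA-to-DNA normalization; Fisher's exact
    gene-set overrepresentation with Bonferroni correction; a binding
    isotherm fit for hormone-inducible reporters; and a generative
    simulator of dual-barcode screens with ground truth, reproducing the
    technical-noise mechanisms of plasmid copy-number variation,
    co-transformation, systemic transcriptional effects, and overdispersed
    sequencing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
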