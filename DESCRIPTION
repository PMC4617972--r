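Package: splicescreen
Title: Junction-Based Alternative Splicing Analysis for RNAi Depletion Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovery, quantification and differential analysis of
    alternative splicing events from splice-junction read counts, designed
    for RNA-seq screens in which many splicing regulators are individually
    depleted by RNAi. Classifies eight event types (cassette exons,
    alternative 5'/3' splice sites, mutually exclusive exons, coordinate
    cassette exons, alternative first/last exons and retained introns) from
    junction BED files and exon annotations, computes percent-spliced-in
    (PSI) from length-normalized isoform abundances, builds a per-event
    virtual reference from cross-sample medians, and calls differential
    splicing with Fisher's exact test under per-event-type
    Benjamini-Hochberg correction. Downstream network statistics summarize
    activation/repression bias per regulator, coordinated versus
    antagonistic regulator pairs, and cross-regulation among the assayed
    splicing-factor genes. A synthetic-data generator with planted ground
    truth supports end-to-end validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
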