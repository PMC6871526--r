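Package: oppeqtl
Title: Detection and Characterization of Tissue-Discordant (Opposite) cis-eQTL Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects primary cis-eQTL signals whose direction of effect on the
    same gene reverses between tissues ("opposite eQTL effects") from per-tissue
    significant variant-gene association tables. For every gene and tissue pair
    the top eQTL SNPs are compared in a 2x2 analysis table, classified by effect
    direction and linkage-disequilibrium (r^2 from a phased reference haplotype
    panel), and aggregated into nested gene/SNP designation sets. Downstream
    enrichment analyses cover transcription-start-site proximity (kurtosis
    permutation test with sharing-matched resampling), epigenetic annotations
    (TSS-distance-matched resampling null), and LD overlap with GWAS-catalog
    SNPs (Fisher and resampling tests). A seeded synthetic-data generator with
    planted ground truth emulates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    data.table,
    jsonlite,
    ape,
    ggplot2,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
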