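Package: tdmeth
Title: Targeted Differential Methylome Analysis of Imprinted Regions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for targeted bisulfite sequencing of large
    regulatory regions, built around a beta-binomial differential
    methylation test with dispersion shrinkage. Provides windowed
    methylation and ATAC-seq profiles, per-CpG differential testing with
    FDR control, bandwidth-based DMR merging, multi-step group-signature
    extraction, calling of hypo- and hypermethylated regions, attribution
    of significant CpGs to genomic elements (promoters, gene bodies,
    enhancers), promoter methylation-index versus expression integration,
    and transcription-factor binding-site enrichment classification.
    Includes a synthetic bisulfite-count generator with planted effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    Sequencing, Coverage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
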