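Package: snpArrayDesign
Title: Design and Validation Pipeline for High-Density SNP Genotyping Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A complete, testable implementation of the computational design of
    a high-density (600k-scale) maize SNP genotyping array: filtering of
    caller-derived sequence variants to a high-confidence bi-allelic candidate
    set, bin-based candidate selection with germplasm-pool quotas, genotype
    calling from two-channel probe intensities with an inbred-penalty
    correction and off-target variant (OTV) detection, cluster-quality metrics
    (FLD, homFLD, HetSO, HomRO) with six-way variant classification, a weighted
    voting system for final array content, and downstream panel analyses
    (Rogers distances and PCoA, minor-allele-frequency spectra, trio Mendelian
    checks, LD pruning and LD-decay estimation). A seeded synthetic-data module
    generates toy genomes, structured inbred panels, sequencing-call records
    and clustered two-channel intensities with planted truth so that every
    stage is testable without external data.
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
    data.table,
    vcfR,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: SNP, Genetics, MicroarrayData, QualityControl, Software
RoxygenNote: 7.3.3
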