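Package: bulkmapr
Title: Bulked-Segregant Trait Mapping with Delta SNP-Index Genome Scans
Version: 0.1.0
Authors@R:
    person("bulkmapr", "developers", email = "bulkmapr@example.org",
           role = c("aut", "cre"))
Description: Conjunctive BSA-Seq and BSR-Seq bulked-segregant analysis for
    F2 populations: per-variant SNP-index and delta(SNP-index) tracks from
    pooled allele depths, sliding-window genome scans with LOESS smoothing
    and simulated 99 percent null thresholds, candidate-region calling and
    gene annotation, intersection of DNA- and RNA-derived candidate gene
    sets, fixed-dispersion negative-binomial exact tests with
    Benjamini-Hochberg FDR for between-bulk differential expression, FPKM,
    and 2^-ddCt relative quantification for qPCR validation panels.
    Includes a seeded F2 cross simulator (Haldane map function, phenotype
    bulking, Poisson/binomial pooled sequencing, negative-binomial counts)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    withr,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
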