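Package: haplotx
Title: Characterising Novel Transcription in GWAS Haploblocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidy toolkit for characterising unannotated transcription in
    linkage-disequilibrium (LD) blocks around GWAS index SNPs. Delineates
    haploblocks from proxy-SNP r2 tables and recombination hotspots, builds
    an exon-depleted capture space, filters assembled transcript models by
    expression and isoform contribution, computes nucleotide- and SNP-level
    enrichment odds ratios with randomised controls, scores tissue
    specificity with the Tau index, produces aggregate (metaplot) profiles
    of CAGE and histone-mark peaks around transcript 5' ends, calls
    bidirectional promoters, and tests allele-specific expression with a
    binomial/Fisher procedure under Benjamini-Hochberg FDR control. A
    seeded synthetic-data generator emulates every input with controllable
    ground truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
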