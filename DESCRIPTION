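Package: milrseek
Title: Discovery of miRNA-Like Small RNAs (milRNAs) in Fungal
    Small-RNA Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting miRNA-like small RNAs
    (milRNAs) from fungal small-RNA libraries and transcript contigs:
    adapter trimming and read collapsing, Nussinov-style RNA hairpin
    folding with stem decomposition, mismatch-tolerant remapping of
    grouped reads onto folded contigs, duplex-based milR/milR* calling
    with library-of-origin classification, conserved miRNA annotation
    against a mature reference, RPKM-based differential expression with
    a binomial proportion test and Benjamini-Hochberg control,
    plant-style (psRNATarget-like) expectation scoring of milRNA
    targets, genomic context classification (intergenic, intron,
    exon-antisense), a k-mer genome-size estimator, and a synthetic
    study generator with a planted-locus truth table for validation.
    Includes the published catalog of 63 Antrodia cinnamomea milRNA
    candidates as a bundled data set.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
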