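Package: rohdiversity
Title: Runs of Homozygosity, Genomic Inbreeding and Within-Breed Diversity from Multi-Sample VCFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for within-breed genomic diversity analysis from
    whole-genome genotypes: sliding-window detection of runs of homozygosity
    (ROH) with a false-discovery calibration of the minimum SNV count,
    genomic inbreeding coefficients (F_ROH) with length-class decomposition,
    discovery and gene annotation of ROH islands shared across individuals,
    linkage-disequilibrium pruning with Hamming-distance multidimensional
    scaling of genetic relatedness, genotyping of breed-relevant trait
    variants and multi-SNV risk haplotypes, and mitochondrial haplotype
    assignment. Includes a synthetic genotype simulator with planted
    autozygous segments and truth tables so every stage is testable without
    external cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
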