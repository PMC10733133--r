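Package: hexaphase
Title: Subgenome Resolution of a Neopolyploid Genome from Joint K-Mer
    Spectra and Assembly Self-Homology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves the three-subgenome organization (one diploid
    homozygous subgenome S and two diverged haplovariants L1, L2 of a
    fused chromosome) of a hidden-polyploid genome. Implements slicing of
    a haploid assembly into paralogous blocks from chained pairwise
    self-alignments with copy-number and divergence statistics; canonical
    k-mer counting and joint 2D frequency spectra of two
    karyotype-differing sequencing libraries; a joint tetraploid/hexaploid
    negative-binomial k-mer spectrum model with shared heterozygosity
    parameters; classification of genomic windows and scaffolds into
    subgenome classes from coverage log-ratios and subgenome-specific
    k-mer counts; and scoring of windows by microdissected-chromosome
    (whole genome amplification) coverage breadth. A synthetic-data
    generator emulates the two-subline experimental design end to end, so
    the whole pipeline is testable without external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    graphics,
    Biostrings,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
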