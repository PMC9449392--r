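Package: sweepscan
Title: Selection-Signature Scans and Population Structure for Diploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based detection of selective sweeps in diploid genomes from
    biallelic SNP data: pooled heterozygosity (Hp), Weir-Cockerham FST averaged
    over sliding windows, nucleotide diversity (theta-pi) log2 ratios, and
    cross-population extended haplotype homozygosity (XP-EHH), with genome-wide
    Z-transformation, threshold- or quantile-based candidate extraction, and
    multi-evidence combination of candidate windows. Includes a
    population-structure layer (allele-sharing distances, neighbour-joining
    trees, Patterson-normalised PCA, LD decay curves), candidate-gene
    annotation with flanked window-gene overlap, and a forward-in-time
    Wright-Fisher simulator generating phased three-population datasets (two
    diverged parents plus an admixed hybrid, with an optional hard sweep at a
    known locus) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    vcfR
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
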