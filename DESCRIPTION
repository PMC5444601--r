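Package: hapblockr
Title: Detection, Genotyping and Dating of Divergent Haplotype Blocks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genomic toolkit for identifying extended,
    non-recombining haplotype blocks (putative chromosomal inversions)
    that segregate between groups of samples, such as highland and
    lowland populations. Provides nucleotide diversity, Watterson's
    theta, dXY, Weir-Cockerham and Reynolds FST estimators; a per-SNP
    FST genome scan with outlier-region delineation; genotype-composition
    based haplotype classification and frequency estimation; neighbor-
    joining trees and windowed quartet-topology analysis; a coalescent
    two-population split-model null simulator for the FST distribution;
    outgroup polarization with synonymous/non-synonymous substitution
    partitioning; molecular-clock dating with window-bootstrap
    confidence intervals; and a fully seeded synthetic-data generator
    with machine-readable truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    vcfR,
    seqinr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
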