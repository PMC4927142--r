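Package: hapblocks
Title: Detection, Calling and Analysis of Extended Haplotype-Genotype Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for discovering extended haplotype-genotype
    blocks (such as those maintained by inversion polymorphisms or other
    recombination-suppressing variation) in phased SNP data. Provides a
    BIC-based linkage-difference scan over candidate breakpoint pairs,
    multi-allelic diplotype calling by multidimensional scaling and k-means
    with diplotype-geometry labeling, a sparse tag-SNP one-dimensional
    fallback caller, Mendelian trio validation and transmission
    disequilibrium tests, population-genetic characterization (tag SNPs,
    Hardy-Weinberg tests, Weir-Cockerham FST, recombination-rate and clinal
    frequency permutation nulls, Hamming-distance neighbor-joining
    phylogenies with outgroup assignment), quantitative-trait and
    cis-expression association under additive and recessive codings, and
    inverse-variance fixed-effects meta-analysis. A synthetic-data module
    generates genotype, trio, phenotype, expression and population-frequency
    fixtures with the assumed block structure so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    ape,
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
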