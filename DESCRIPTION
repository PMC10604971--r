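Package: epigblup
Title: Multifactorial Genomic Prediction with Epistatic and Haplotype
    Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component estimation (AI-REML with EM fallback) and
    genomic best linear unbiased prediction (GBLUP) under a multifactorial
    mixed model with SNP additive and dominance effects, global epistasis
    effects up to fourth order (approximate Hadamard-product and exact
    intra-locus-corrected genomic relationship matrices), and
    haplotype-block additive effects.  Includes the three haplotype
    blocking schemes (fixed SNP count, fixed bp window, gene regions),
    10-fold cross-validation of predictive ability, heritability-threshold
    initial model selection followed by accuracy-based final selection,
    GCTA-format relationship-matrix IO, and a synthetic-data generator
    producing phased LD-blocked genotypes and phenotypes with configurable
    additive, dominance, pairwise-epistatic and block-local high-order
    genetic architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
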