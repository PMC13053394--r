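Package: PleioGWAS
Title: Single-Step GWAS and Multi-Trait Pleiotropy Meta-Analysis for
    Correlated Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the complete computational chain of a single-step
    genomic BLUP (ssGBLUP) association study for repeated-record quantitative
    traits together with a multi-trait (pleiotropy) meta-analysis and
    window-based gene/QTL annotation. Provides pedigree (A, A-inverse with
    inbreeding), genomic (VanRaden G) and combined (H-inverse) relationship
    matrices, Henderson mixed-model equations for the repeatability animal
    model, SNP-effect back-solving from genomic breeding values with
    normal-theory p-values and chromosome-wise Bonferroni thresholds based on
    the effective number of independent chromosomal segments, Cholesky
    decorrelation of correlated traits with the signed-t multi-trait
    chi-square statistic, and QTL-category enrichment with FDR control.
    Includes a seeded forward simulator (pedigree, linked genotypes, repeated
    phenotype records with known QTL architecture) so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
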