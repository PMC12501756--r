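Package: hapsel
Title: Mendelian Sampling Variance, Haplotype Similarity Matrices and
    Optimal Contribution Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast analytical prediction of Mendelian sampling (co)variances of
    gamete and zygote breeding values from phased biallelic genotypes, a
    genetic map and additive marker effects; trait-specific haplotype
    similarity matrices between parents (gametic and zygotic, single-trait,
    multi-trait and aggregate-genotype) with standardisation and
    nearest-positive-semidefinite repair; a quadratically constrained optimal
    contribution optimiser that maximises expected genetic return under a
    constraint on average haplotype similarity (or genomic coancestry); an
    exact segregation-pattern enumeration oracle for small instances; and a
    compact stochastic breeding-program simulator for comparing truncation
    selection with similarity-constrained contribution selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
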