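Package: singlestep
Title: Single-Step Genomic Prediction with Pedigree, Genomic and Combined
    Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for genomic evaluation of livestock populations by
    pedigree-based BLUP, genomic BLUP (GBLUP), and single-step GBLUP
    (ssGBLUP) in single-trait and two-trait animal models. Builds the
    numerator relationship matrix A and its sparse inverse from a
    pedigree, the VanRaden genomic relationship matrix G from SNP
    dosages, and the combined relationship matrix H that joins genotyped
    and non-genotyped animals, including the scale adjustment of G to
    the pedigree base and the weighted blend used to keep H invertible.
    Includes marker quality control (minor allele frequency, call rate,
    Hardy-Weinberg equilibrium), Henderson mixed-model-equation solvers,
    EM-REML variance-component estimation, a forward-in-time
    quantitative-trait simulator with linked markers and QTL, and a
    replicated k-fold cross-validation harness reporting prediction
    accuracy and unbiasedness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
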