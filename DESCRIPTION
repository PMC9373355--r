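Package: dimorphQTL
Title: Sex-Stratified cis-eQTL Mapping, Sex-Difference Statistics,
    Transcriptome-Wide Mendelian Randomization and Power Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying sex dimorphism in the genetic regulation of
    gene expression and its downstream consequences on complex traits.
    Implements sex-stratified cis-eQTL mapping by rank correlation within a
    +/- 1 Mb window with principal-component correction, z/t statistics for
    differences between female- and male-specific eQTL and GWAS effects,
    expression mean and variance dimorphism tests, Benjamini-Hochberg FDR
    selection and lead-eQTL choice, multivariable summary-statistic
    transcriptome-wide Mendelian randomization (TWMR) run per sex with a
    sex-contrast on the causal effect, and the analytic power and
    sample-size model for sex-biased trait associations mediated by
    sex-biased eQTLs. A synthetic-data generator produces genotypes,
    expression, traits and summary statistics with known ground truth under
    configurable null and sex-biased scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
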