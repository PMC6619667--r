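Package: hybridmisreg
Title: Gene Misregulation, Inheritance and Allele-Specific Expression in F1 Hybrids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gene-expression misregulation in F1 hybrids
    from bulk RNA-seq read counts. Implements median-of-ratios normalisation,
    a negative-binomial Wald test for two-group differential expression,
    classification of hybrid inheritance modes (conserved, additive, dominant,
    over-/underdominant), allele-specific expression tests at shared
    heterozygous sites (per-site exact binomial and a pseudo-phasing
    simulation test at the gene level), identification of putative
    compensatory cis-trans regulatory divergence, and correction of
    misregulation estimates for library-preparation batch bias, including
    transcript-integrity (TIN) degradation diagnostics. A fully seeded
    synthetic-data generator with known truth labels supports calibration and
    power analysis of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
biocViews: RNASeq, DifferentialExpression, GeneExpression, Regression
RoxygenNote: 7.3.3
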