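Package: regqtl
Title: Screening for Genetic Variants that Modulate miRNA-mRNA
    Regulatory Interactions
Version: 0.1.0
Authors@R:
    person("regqtl", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Genome-scale interaction-QTL ("regQTL") screening. For every
    candidate (miRNA, gene, SNP) trio drawn from dysregulated
    miRNA-pathway pairs, fits a linear model of gene expression on miRNA
    expression, categorical SNP genotype, their interaction, and the
    first two genotype principal components as population-structure
    covariates; tests the genotype-by-miRNA interaction with a Type III
    ANOVA partial F-test; removes high-influence samples (Cook's
    distance > 1) and refits; and controls the false discovery rate over
    all tested trios with the Benjamini-Hochberg step-up procedure.
    Includes the expression and genotype preprocessing filters, a
    synthetic-cohort generator for null, power, population-substructure
    and outlier-contamination scenarios, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    optparse,
    yaml,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
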