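Package: maturix
Title: Mixed-Model Differential Expression and Multivariate Integration
    for Factorial Fetal Transcriptome Studies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical workflow for identifying maturity-associated genes
    in a two-age by four-genotype reciprocal-cross fetal design. Provides
    per-probe linear mixed models with a random litter (sow) effect and an
    F-type test with Satterthwaite degrees of freedom, Benjamini-Hochberg
    FDR control, BIC-based assignment of differential probes to four
    fixed-effect sub-models, a parental-genome reparameterization separating
    maternal from paternal effects, sparse partial least squares integration
    of the transcriptome with phenotypic variables (Q2 tuning, MSEP/R2
    diagnostics, relevance networks), two-way ANOVA of phenotypes with
    Box-Cox transformation, geNorm reference-gene stability and qPCR
    validation statistics, and hypergeometric gene-set enrichment. A
    synthetic-data generator with planted truth makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    car
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    lmerTest,
    mixOmics,
    MASS,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, DifferentialExpression, Microarray,
    Regression, Network
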