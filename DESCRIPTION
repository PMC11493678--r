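Package: noncogdev
Title: Developmental Genetics of Cognitive and Non-Cognitive Contributions to Academic Achievement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end, fully synthetic re-implementation of a developmental
    behaviour-genetic analysis pipeline linking cognitive and non-cognitive
    skills to academic achievement across the school years. Provides a
    simulator for twin cohorts with block-LD genotypes, direct and indirect
    (parental) genetic effects and a developmental amplification schedule;
    one-factor confirmatory factor analysis and standardized regressions;
    maximum-likelihood twin ACE, common-pathway and trivariate Cholesky
    models; LD-score regression and a GWAS-by-subtraction genomic structural
    equation model yielding per-SNP cognitive and non-cognitive effects;
    LDpred-infinitesimal polygenic scores; and population-level,
    within/between-family and gene-environment-interaction polygenic-score
    regressions with cluster-robust inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    sandwich,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
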