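Package: telosig
Title: Telomere-Length Genetic Epidemiology Toolkit: Mendelian
    Randomisation, Colocalisation, LD-Score Regression and Tumour
    Expression Signatures
Version: 0.1.0
Authors@R:
    person("telosig", "developers", email = "telosig@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for interrogating the relationship between
    a genetically proxied exposure (leukocyte telomere length) and disease
    outcomes (lung cancer subtypes) from GWAS summary statistics:
    instrument selection and allele harmonisation, a two-sample Mendelian
    randomisation estimator battery (IVW with multiplicative random
    effects, MR-Egger, weighted median, contamination mixture,
    multivariable MR) with heterogeneity and leave-one-out diagnostics,
    approximate-Bayes-factor colocalisation with conditioning/masking and
    simplified multi-trait clustering, cross-trait LD-score regression
    with block-jackknife uncertainty, polygenic risk scoring, and a
    tumour-transcriptome arm (count normalisation, expression PCA,
    Procrustes alignment, LASSO gene signatures). Ground-truth simulators
    make every stage verifiable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
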