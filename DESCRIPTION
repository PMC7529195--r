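Package: cliphet
Title: Heterogeneity Tests for Polygenic Risk Score Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects hidden heterogeneity in GWAS cohorts by comparing
    SNP-SNP correlations among cases against controls, corrected for the
    negative correlations expected of homogeneous cases ascertained under a
    liability threshold model. Provides the case/control test, extensions
    for continuous predictors such as imputed expression and for
    quantitative phenotypes with learned phenotype-weighting functions,
    generative cohort simulators (misclassification, disease subtypes,
    population stratification, expression-mediated and quantitative
    designs), meta-analytic combiners, and delimited-format input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
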