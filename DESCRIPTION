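Package: snpfrr
Title: Familial Relative Risk and Cross-Validated Risk Prediction for SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate the clinical usefulness of genome-wide-significant
    susceptibility SNPs for a disease. Implements the multiplicative genotype
    relative-risk population model (Hardy-Weinberg genotype distributions in
    cases and controls, Bayes-optimal likelihood-ratio risk scores, and the
    exact enumerated AUC ceiling of a SNP panel), the per-locus familial
    relative risk statistic and the proportion of overall familial risk it
    explains, estimation of locus parameters from case-control genotype counts
    with bootstrap confidence intervals, a synthetic case-control cohort
    generator with gender/age covariates and matched resampling, and a
    stratified 10-fold cross-validation harness with native classifiers and
    AUC/sensitivity/specificity/accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
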