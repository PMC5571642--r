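Package: pleioscan
Title: Multivariate GWAS for Correlated Phenotypes in Related Samples via
    Mixed Models and Fisher Combination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step multivariate genome-wide association testing for
    correlated quantitative phenotypes measured on related and/or admixed
    subjects. Step one fits a single-kernel linear mixed model per phenotype
    with a genetic relationship matrix random effect (spectral REML) and
    computes per-SNP Wald tests with plugged-in variance components. Step two
    combines the marginal p-values per SNP with the Fisher statistic, whose
    null distribution under dependence is a moment-matched gamma calibrated
    from the cross-trait correlation of the mixed-model residuals via a
    polynomial covariance approximation. Includes a pedigree/admixture
    genotype simulator, a multivariate-normal phenotype simulator, PLINK and
    GCTA-GRM file support, quality-control filters, and scripted simulation
    experiments for type I error, power, and correlation-estimator accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
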