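Package: mvgwas
Title: Multivariate ANOVA Association Testing for Dose-Response Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide association testing for individuals with multivariate
    dose-response phenotypes, such as cell-line viabilities measured across a
    series of drug concentrations. Each SNP is tested with a multivariate
    analysis of variance (MANOVA) using Pillai's trace and its F
    approximation, with support for confounding covariates and PLINK 1 binary
    genotype files. Also provides the classical univariate comparison methods
    (per-curve IC50 and slope from four-parameter logistic fits, empirical
    area under the curve, and pooled-observation ANOVA), a dose-response
    simulation framework with configurable mean profiles, covariance
    structures and error families, and power / type-I-error study machinery
    with resampling p-values and QQ calibration diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
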