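Package: gatetest
Title: Group Accumulated Test Evidence for Pleiotropic Genetic Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests for association between a single genetic variant and
    multiple correlated quantitative traits.  Principal components of the
    trait covariance matrix are each regressed on the additive genotype,
    the per-component Wald statistics are combined in contiguous groups by
    Fisher's method, and the group-accumulated statistic (GATE) takes the
    best grouping over group counts, with significance obtained from a
    one-layer standard-normal resampling null that is shared across
    variants.  Includes the classical comparators (Fisher-combined test,
    multistep combined principal component test, MANOVA, TATES, and a
    proportional-odds reverse regression), latent-factor simulation models
    for correlated phenotypes, power/type-I-error study drivers, and a
    genome-scan interface over TSV or VCF genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    flexsurv,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
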