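Package: cbkit
Title: Clustering and Burden Association Tests and Mutational Hotspot
    Models for Rare Missense Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for rare missense variants in Mendelian
    disease genes. Implements the BIN-test (a binned chi-squared two-sample
    test for differential positional clustering of case versus control
    variants along the linear protein sequence), a one-sided carrier burden
    test, and their Fisher's-method combination (ClusterBurden), with
    optional adjustment for uneven sequencing coverage. Provides penalized
    spline binomial generalised additive "hotspot" models that convert
    gene-level burden and residue position into per-residue odds ratios
    with confidence intervals and ACMG-style evidence strata, and
    "hotspot+" extensions that add in-silico predictor scores through a
    strict two-stage feature selection. A forward-style case-control
    simulator, power and type-I-error estimation utilities, and
    tab-separated readers and writers round out the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
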