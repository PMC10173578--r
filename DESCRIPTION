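Package: netMR
Title: Network Mendelian Randomization with Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-sample summary-data Mendelian randomization for causal
    networks of one exposure, several candidate mediators and an outcome.
    Reads and harmonizes GWAS summary statistics, selects independent
    genome-wide-significant instruments by LD clumping, estimates causal
    effects with the inverse-variance-weighted, MR-Egger, maximum-likelihood
    and robust-adjusted-profile-score estimators, runs heterogeneity,
    pleiotropy, outlier (MR-PRESSO style), directionality (Steiger) and
    power diagnostics, and decomposes total effects into direct and
    mediated components with proportions mediated via multivariable MR.
    Includes a synthetic summary-statistics generator with known causal
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
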