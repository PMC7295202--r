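Package: mrbattery
Title: Two-Sample Mendelian Randomization Estimator Battery with Pleiotropy Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: harmonization of exposure and outcome association sets to a
    common effect allele, inverse-variance weighted, MR-Egger, weighted median
    and mode-based causal-effect estimators, an unweighted allele-score
    fixed-effects meta-analysis, SIMEX correction of MR-Egger regression
    dilution under measurement error, instrument-strength and heterogeneity
    diagnostics (Cochran's Q, I2GX, mean F), radial-MR outlier detection and
    leave-one-out analysis. Includes derivation of covariate-adjusted per-SNP
    outcome associations from individual-level tables and a synthetic-data
    generator emulating the statistical structure of reproductive life-history
    GWAS instruments, so the full battery is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
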