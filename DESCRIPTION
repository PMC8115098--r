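Package: ivmr
Title: Two-Sample Mendelian Randomisation with Pleiotropy-Robust Estimators
    and Latent Causal Variable Modelling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for two-sample Mendelian randomisation from
    GWAS summary statistics: reading, validation and munging of summary
    tables; instrument selection, LD clumping, allele harmonization and
    instrument-strength (F statistic) quantification; a suite of causal-effect
    estimators (inverse-variance weighted with multiplicative random effects,
    MR-Egger, weighted median, weighted mode, MR-PRESSO outlier correction,
    and a correlated-instrument generalised least squares IVW); heterogeneity,
    pleiotropy, leave-one-out and Steiger directionality diagnostics with
    liability-scale conversions for binary traits; a latent causal variable
    model estimating the genetic causality proportion from genome-wide
    summary statistics; and a synthetic summary-statistics generator with
    known causal truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
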