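Package: epochmr
Title: Longitudinal Two-Sample Mendelian Randomisation Across Age Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-sample Mendelian randomisation for time-varying exposures
    measured at multiple ages, built around the analysis of standardised
    childhood BMI and multiple sclerosis susceptibility. Provides GWAS
    summary-statistic input/output with validation, instrument construction
    (genome-wide significance filtering, greedy LD clumping against a user
    supplied LD matrix, MHC exclusion, amalgamation of time points into age
    epochs by smallest p value), exposure/outcome harmonisation with
    palindromic-SNP policies, the full univariable estimator suite
    (Wald ratio, fixed and multiplicative-random-effects IVW, MR-Egger,
    weighted median, simple and weighted mode), Cochran's Q, per-SNP F
    statistics, Steiger filtering, leave-one-out analysis, the MR-PRESSO
    global, outlier and distortion tests, residual-based and joint
    multivariable MR, a Mann-Kendall trend test across time points, a
    synthetic summary-statistic generator with known causal structure, and
    an end-to-end pipeline producing a per-epoch results report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
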