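Package: mrpipe
Title: Two-Sample Mendelian Randomization for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    GWAS summary statistics: reading, validation and allele harmonization of
    per-variant association tables; instrument selection by genome-wide
    significance, greedy LD clumping and per-variant F-statistics; causal
    estimation by Wald ratio, fixed- and random-effects inverse-variance
    weighting, MR-Egger regression with intercept-based pleiotropy testing,
    weighted median and weighted mode with bootstrap standard errors, and
    multivariable IVW; MR-PRESSO global, outlier and distortion tests;
    cis drug-target MR with trait-lowering orientation; heterogeneity-gated
    fixed/random-effects meta-analysis across cohorts with Bonferroni
    screening; and a fully seeded synthetic GWAS summary-statistic generator
    with known ground truth for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
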