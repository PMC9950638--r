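Package: bidirmr
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization with
    GWAS summary statistics: reading and harmonizing per-SNP association
    records (strand correction, palindromic-SNP removal), instrument selection
    and quality control (two-tier significance thresholds, greedy LD clumping,
    proxy substitution, mean F-statistics, confounder screening, Steiger
    directionality filtering), causal-effect estimation (Wald ratio,
    inverse-variance-weighted with fixed or multiplicative random effects,
    MR-Egger, weighted median, MR-PRESSO outlier resampling, Cochran Q and
    I-squared heterogeneity), fixed and DerSimonian-Laird meta-analysis across
    outcome sources, and a seeded synthetic summary-statistics generator with
    known ground truth for calibration and robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
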