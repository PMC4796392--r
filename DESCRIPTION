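Package: mmcompare
Title: Statistical Comparison of Molecular Modeling Methods
Version: 0.1.0
Authors@R:
    person("mmcompare", "maintainers", email = "mmcompare@example.org",
           role = c("aut", "cre"))
Description: Correlation-aware statistical comparison of prediction methods
    in computational chemistry and virtual screening. Provides error bars on
    differences of means, AUCs, ROC enrichments and Pearson correlations for
    both independent and paired (correlated) designs; asymmetric-interval
    arithmetic; family-wise multiple-comparison procedures (Holm-Bonferroni,
    Hochberg); one-way and covariance-whitened ANOVA with Tukey HSD;
    effect-size measures (Cohen's d, probability of superiority) and minimum
    Bayes odds recalibration of p-values; plus seeded synthetic-data
    generators for calibration studies and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
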