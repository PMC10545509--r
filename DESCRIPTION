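Package: vocometrics
Title: Noise-Vocoded Speech Intelligibility Psychometrics and Group
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of noise-vocoded speech perception
    experiments: a channel vocoder for degrading speech-like audio, a
    synthetic listener and cohort simulator, positional digit scoring,
    maximum-likelihood fitting of Weibull psychometric functions with
    guess and lapse asymptotes and beta-binomial overdispersion,
    nonparametric group statistics (Kruskal-Wallis with eta-squared
    effect sizes, Dunn post hoc tests, Spearman correlation, quantile
    outlier flagging), and ROC-based diagnostic discrimination of the
    50 percent intelligibility threshold between clinical groups and
    controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    pROC,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
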