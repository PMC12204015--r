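Package: hsrglyc
Title: Whole-Blood Heat Shock Response and Glycaemic Status Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links the ex-vivo whole-blood heat shock response statistic
    (delta-HSP70, the round-normalized HSP70/GAPDH expression at 42 degrees
    Celsius minus its paired 37 degree control) to glycaemic status in
    longitudinal rodent cohorts. Implements two-stage densitometry
    normalization, HOMA-IR and QUICKI surrogate indices with clinical
    status classification, incremental areas under glucose- and
    insulin-tolerance curves with geometric baseline-crossing correction,
    asymmetric five-parameter logistic regression with inverse threshold
    prediction and likelihood-ratio pseudo-R-squared goodness of fit,
    linear trends with onset-crossing times, and a seeded synthetic cohort
    generator for end-to-end parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
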