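Package: twinEEA
Title: Twin-Pair Similarity in Childhood Social Adversity and the
    Equal-Environment Assumption
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fixed-weights meta-analysis of intraclass correlations for
    childhood social adversity in monozygotic and dizygotic twin pairs.
    Implements Fisher's r-to-z comparison of two independent correlations
    with one-tailed tests, pair-count-weighted pooling of correlations
    into adversity constructs and moderator subgroups, intraclass
    correlation estimators for pair-level exposure data, a synthetic
    twin-corpus generator for calibration and power studies, and a
    variance-components (ACE) model quantifying how unequal environmental
    correlations between zygosity groups bias Falconer-type heritability
    estimates. Ships the study-level correlation tables of a published
    11-study corpus (9119 twin pairs) as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
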