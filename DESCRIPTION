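Package: worthtree
Title: Loglinear Bradley-Terry Trees for Ranking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of worth parameters from complete rankings via the
    loglinear Bradley-Terry pattern model, with model-based recursive
    partitioning over subject covariates to uncover preference heterogeneity.
    Rankings of J items are converted to transitive paired-comparison
    patterns and fitted as a J!-cell multinomial exponential family;
    heterogeneity is detected by score-fluctuation (supLM) parameter
    instability tests, trees are stabilized by AIC post-pruning, and split
    stability is quantified by a nonparametric bootstrap. Includes a
    synthetic-data generator emulating ranking studies with covariate-defined
    subgroups, a focal-group extension of the model, and JSON/DOT/CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
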