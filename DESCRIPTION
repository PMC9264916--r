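Package: ledscreen
Title: Lethal Dependency Discovery from Loss-of-Function Screens with
    Hub-Grouped Multiple Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies lethal dependencies (LEDs) between gene alterations
    and gene-knockout essentiality in CRISPR/RNAi loss-of-function screens.
    Essentiality differences between mutant and wild-type cell lines are
    tested with an empirical-Bayes moderated t-test, and multiple testing
    is corrected by grouping tests per altered gene (the "hub effect" of a
    few alterations on many knockouts) with per-group local false discovery
    rates and a covariate-weighted Benjamini-Hochberg procedure. Includes
    classical baselines (ANOVA with Storey-Tibshirani q-values, Bonferroni,
    Holm), threshold-based LED calling with positive/negative/dual
    classification, validation against clinical-association knowledge bases
    and gene-gene relation networks, and a synthetic-screen simulator with
    known ground truth for power and false-discovery-rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
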