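Package: mrsuite
Title: Two-Sample Mendelian Randomization with Simulation-Backed Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian randomization
    from GWAS summary statistics: instrument selection by significance
    threshold and greedy LD pruning, effect-allele harmonization with a full
    audit trail, the standard causal-estimator battery (Wald ratios,
    inverse-variance-weighted meta-analysis with a fixed/random-effects
    heterogeneity switch, weighted median, weighted mode, MR-Egger,
    contamination mixture, MR-PRESSO outlier testing), likelihood-based
    clustering of variant-specific estimates into substantive, null, and junk
    clusters, Benjamini-Hochberg FDR control across exposure families, and
    analytic power calculation. A synthetic two-sample summary-statistics
    generator with known ground truth (configurable causal effect, pleiotropy
    scenarios, LD blocks, and allele-coding pathologies) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
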