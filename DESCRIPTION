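Package: synergyscan
Title: Pathway-Level Association Scanning for Drug-Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Scores drug-pair dose-response screens with a modified-Bliss
    ComboScore, builds gene- and pathway-level features from transcriptome
    presence calls, RNAi dependency (D2) scores and drug-target maps, fits
    per-pair logistic association models (gene-level and three pathway
    analyses) with a Firth-penalized fallback, aggregates p-values by
    minimum-p with Bonferroni thresholds and expected/observed FDR tables,
    and validates pathway signals with Wilcoxon rank-sum tests. Includes a
    synthetic-study generator with planted pathway-driven synergy so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
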