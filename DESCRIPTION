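Package: tmshet
Title: Heterogeneity Scoring and Drug-Response Analysis for 2D, 3D and
    Xenograft Breast Cancer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis layer for comparing monolayer (2D), 3D
    spheroid, 3D-bioprinted tissue-mimetic scaffold (TMS) and xenograft
    breast-cancer models. Scores immunostaining intratumoural heterogeneity
    (H-score, Shannon Diversity Index, cohort-level >40% heterogeneity calls),
    normalizes viability assays to control %, computes combination indices
    with synergy classification and four-band drug-sensitivity calls, scores
    cross-model concordance, summarises caliper-based xenograft growth, and
    ships calibrated synthetic-data generators so the whole pipeline is
    testable end to end without raw measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
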