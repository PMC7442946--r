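Package: peerma
Title: Agreement Analysis for Paired Ecological and Peer-Ceived Momentary
    Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dyadic self-other agreement in experience
    sampling studies that pair ecological momentary assessments (EMA) from a
    participant with peer-ceived momentary assessments (PeerMA) from a
    designated peer. Provides long-format readers and validators for momentary
    assessment tables, per-person min-max normalization, derived well-being,
    daily aggregation with explicit missingness, spline imputation for
    plotting, participation and per-person profile summaries, mean directional
    accuracy with same-day and same-or-next-day matching, tie-corrected
    Spearman rank correlations with strength classification, Wilcoxon
    signed-rank equality testing with statistical-equality fractions, MAAPE
    residuals, and a seeded generator of synthetic dyadic studies with known
    coupling, bias, lag, and response rates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
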