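Package: screenome
Title: Screen-Text and Momentary-Assessment Risk Profiling for Intensive
    Smartphone Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds daily suicide-risk profiles from passively captured
    smartphone screen text ("screenomes") and ecological momentary
    assessment (EMA) self-reports. Provides OCR-confidence filtering and
    text normalization, phrase-lexicon scoring with daily and hourly
    aggregation, app-category tagging and social-content aggregation,
    EMA compliance and composite suicide scores with person-specific
    high-score flagging, phone-use matrices derived from 5-second capture
    timestamps, hospitalization-aligned person-day profile tables with
    loess trend smoothing, and a fully parameterized synthetic-data
    generator so that every stage is testable without access to protected
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
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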