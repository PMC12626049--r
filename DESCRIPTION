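Package: pilappraise
Title: Appraisal of Patient Information Leaflets by Readability and Weighted Composite Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for appraising patient information leaflets (PILs):
    structure-only text standardisation so bullets, headings and flattened
    tables parse as complete sentences; four readability indices
    (Flesch-Kincaid Grade, Flesch Reading Ease, Automated Readability Index,
    Gunning Fog) computed from explicit token, sentence and syllable counts;
    ingestion and validation of human-assigned instrument scores (DISCERN,
    PEMAT-P understandability/actionability, a 0-6 misinformation rubric,
    referencing quality); hybrid min-max normalization with pre-declared
    weights and composite percentage ranking; rank-stability sensitivity
    analysis across alternative scalings; and a seeded synthetic corpus
    generator for testing every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
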