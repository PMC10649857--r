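Package: delphivalidity
Title: Content Validity Analysis for Delphi Expert Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative side of questionnaire content
    validation with Delphi expert panels: the item-level content validity
    index (I-CVI), the chance-corrected modified kappa, Aiken's V with
    score-method (Wilson-type) confidence intervals, comprehensibility
    banding of mean clarity ratings, and a multi-round item-selection
    pipeline with an auditable disposition ledger and manual-override
    support (duplicate merges, relevance exclusions, forced inclusions,
    reformulations). Includes a calibrated latent-trait simulator of
    expert rating panels with attrition, so every pipeline stage is
    testable without survey data, and a per-item validity fixture from
    the 42-item Chem-Sex Inventory (CSI) expert panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
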