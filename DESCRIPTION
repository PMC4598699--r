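Package: ampmyield
Title: Daily Milk and Fatty-Acid Yield Prediction from a Single (AM or PM) Milking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for alternate (AM/PM) milk-recording schemes in dairy cattle.
    Implements the selection-index decomposition of 50/50 composite test-day
    samples into expected morning and evening phenotypes, class-nested linear
    prediction models for 24-h milk, fat and fatty-acid-group yields from a
    single milking without a milking-interval term, forward stepwise model
    selection against held-out test and validation sets, the associated
    goodness-of-fit and validation statistics, and a nested-regression analysis
    of how much milking-interval variation is explained by routinely recorded
    production traits. A synthetic test-day generator with known ground truth
    (Wood lactation curves, interval-driven milking splits, dilution of fat
    content, seasonal fatty-acid composition) supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
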