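Package: qolindex
Title: Entropy-Weighted Quality-of-Life Index Construction and Panel
    Analysis for Provincial Aging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the quality of life of the oldest-old
    (persons aged 80 and above) across provincial units under the active
    aging framework of health, participation and security. Provides an
    abridged current (period) life table for the life-expectancy
    indicator, min-max standardization with indicator polarity, entropy
    weighting and aggregation into dimension and overall composite
    scores, coefficient-of-variation regional disparity measures,
    Fisher-Jenks natural-breaks level classification with grade
    transition accounting, fixed- and random-effects panel regression
    with a Hausman specification test, and a seeded synthetic-data
    generator for provincial indicator and covariate panels so the whole
    pipeline can be exercised and validated without restricted yearbook
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
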