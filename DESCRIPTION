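Package: metamorph
Title: Growth-Curve Model Selection and Endpoint Analysis for Larval
    Rearing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for factorial larval-rearing experiments in which
    density, salinity, and population of origin act on tadpole growth and
    metamorphosis. Fits Gompertz growth curves to cup-mean total length by
    maximum likelihood, with treatment-structured maximum growth rate
    (gamma) and growth-rate decay (alpha), and compares all 17
    parameterizations (additive and interactive treatment structures plus
    a no-effects model) by small-sample-corrected AIC with Akaike weights.
    Metamorphosis endpoints (survival, age, and length at metamorphosis)
    are analysed with block random-intercept generalized linear mixed
    models and likelihood-ratio backward elimination. A synthetic-data
    generator reproduces the full 3 density x 2 salinity x 2 location x 6
    block design so the whole pipeline is testable without the original
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
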