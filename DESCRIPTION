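Package: salmonMO2
Title: Oxygen Consumption Modelling for Farmed Atlantic Salmon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and applies a multiplicative fundamental model for the
    mass-specific oxygen consumption rate (MO2, mg O2 per kg per hour) of
    seawater-adapted Atlantic salmon as a function of body weight, water
    temperature and relative swimming speed. Provides inclusion and
    model-assumption filters for compiled group swim-tunnel respirometry
    data, a two-stage estimation procedure (log-linear start values followed
    by maximum-likelihood nonlinear mixed-effects with a per-study random
    intercept), interaction screening, Wald intervals, fit diagnostics,
    legacy-model comparison, Q10 and coefficient contrasts, delta-method
    prediction bands, a guardrailed prediction interface encoding
    extrapolation limits, and a seeded synthetic-data generator that
    emulates the statistical structure of the compiled dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
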