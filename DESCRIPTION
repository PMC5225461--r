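Package: trainsignal
Title: Secondary-Signal Dose-Response Models of Training and Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Indirect-response (secondary-signal) models of the dose-response
    relationship between daily training load and physical performance.
    Implements the four model variants T, TI, TF and TIF as discrete daily
    recursions, maximum-likelihood fitting with multi-start optimisation,
    the full model-selection battery (R2, adjusted R2, AICc, Akaike weights,
    nested F-ratio tests), steady-state dose-response analysis with optimal
    daily dose estimation, session-interaction simulations, and a generator
    of protocol-faithful synthetic subjects emulating a 15-week cycling
    training study. Includes CSV input/output for daily load/performance
    series and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
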