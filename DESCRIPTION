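Package: smartrar
Title: Response-Adaptive Randomization for Sequential Multiple Assignment
    Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to design, simulate, and analyze sequential multiple
    assignment randomized trials (SMARTs) under response-adaptive
    randomization driven by Thompson sampling over frequentist confidence
    distributions.  Supports up-front randomization to embedded treatment
    regimes and sequential per-stage randomization via Q-learning with
    projection-style confidence draws; inverse probability weighted and
    augmented estimators of embedded-regime values with variance-stabilizing
    weights and martingale-based normal-theory inference; and a Monte Carlo
    harness for operating characteristics of candidate designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
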