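Package: mmrimpact
Title: Scenario Projections of Maternal Mortality Under Intervention
    Coverage Scale-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the impact of scaling up maternal health intervention
    coverage on the maternal mortality ratio (MMR) in low- and middle-income
    countries. Implements the Lives Saved Tool (LiST) style cause-and-
    intervention arithmetic (estimated MMR and additional maternal lives
    saved from cause-of-death shares, intervention efficacy, affected
    fraction and coverage change), four coverage scale-up scenarios,
    joinpoint regression on log-MMR with annual percent change (APC) and
    average APC (AAPC) plus a stall/increase trend classification,
    80 percent uncertainty-interval propagation, births-weighted regional
    aggregation, and a seeded synthetic country-panel generator emulating
    the structure of the WHO/GBD/LiST inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
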