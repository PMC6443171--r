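Package: clutchwork
Title: Clutch-Schedule Statistics, Cohort Round Inference and Monte Carlo
    Simulation of Leech Reproductive Life Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing reproductive life histories of iteroparous
    glossiphoniid leeches (genus Helobdella) and similar brooding
    invertebrates. Computes per-clutch-number and inter-clutch interval
    statistics from individuals reared in isolation, infers reproductive
    rounds in interbreeding cohorts by the quota counting rule, builds
    pseudo-cohorts from pooled individual records, and simulates
    reproductive event schedules with a seeded Monte Carlo model whose
    parameters are estimated from individual records, inferred cohort
    rounds, or published summary tables. Includes a synthetic ground-truth
    data generator for studying round-inference error modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
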