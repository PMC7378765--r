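Package: vaxgame
Title: Evolutionary Game Dynamics of Vaccine-Manufacturer Self-Discipline
    under Government Regulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-population asymmetric evolutionary game between vaccine
    manufacturers (self-discipline versus non-self-discipline) and a
    government regulator (active versus passive supervision).  Implements
    the bimatrix payoff structure, replicator dynamics on the unit square,
    enumeration of equilibria with Jacobian-based stability classification,
    parameter-regime analysis, phase-portrait and parameter-sweep
    experiments, and a bisection-based finder for the critical fine at
    which the temptation of non-self-discipline equals the passive-channel
    detection probability.  A small command-line interface supports
    reproducible batch runs with CSV/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
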