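Package: pyrekin
Title: Branched First-Order Kinetics of Parent-Metabolite Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing microbial degradation time courses in which a
    parent compound (e.g. the four-ring PAH pyrene) decays by first-order
    kinetics and a fraction of the degraded flux accumulates transiently as a
    tracked intermediate metabolite (e.g. 2,2'-diphenic acid). Provides the
    closed-form (Bateman) and numerical solutions of the branched two-pool
    model, global nonlinear least-squares fitting of paired parent and
    intermediate series, parametric bootstrap percentile intervals for the
    rate constants and the branching fraction, molar-yield stoichiometry,
    2^-delta-delta-Ct relative expression from RT-qPCR Ct tables, and a
    seeded synthetic-data generator emulating triplicate sampling with
    limit-of-detection censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
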