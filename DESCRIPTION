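Package: scblock
Title: Stochastically Curtailed Block-Randomised Two-Arm Trial Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and exact evaluation of two-arm randomised phase II
    clinical trials with a binary outcome that use stochastic curtailment
    within a block-randomised allocation scheme.  Conditional power is
    computed by an exact backward binomial recursion over block-end states,
    so that go/no-go stopping boundaries, type I error, power, expected
    sample size and the full stopping-time distribution of a design are
    known without simulation error.  Includes an admissible-design search
    over final boundaries, maximum sample sizes and conditional-power
    thresholds; exact evaluation of the single-arm two-stage design of
    Simon, the randomised two-stage design of Jung and the curtailed
    designs of Carsten & Chen and Chen et al. for benchmarking; loss-score
    comparison of design approaches over a weight simplex; rejection
    probability surfaces under misspecified response rates; and a seeded
    Monte Carlo trial simulator that serves as an independent check on
    every exact computation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
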