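Package: optifut
Title: Optimized Non-Binding Futility Boundaries for Two-Stage
    Single-Arm Binomial Trials
Version: 1.0.0
Authors@R:
    person("Rowan", "Hartley", email = "rowan.hartley@example.org",
           role = c("aut", "cre"))
Description: Exact design calculations for single-arm phase II trials with a
    binary endpoint and one interim futility analysis.  Provides exact
    binomial operating characteristics (type I error, power, probability of
    early termination, expected sample size) for arbitrary two-stage designs
    (r1, n1, r, n), exhaustive-search derivation of Simon's optimal and
    minimax designs and of Kim's modified variants, and an algorithm that
    derives optimized non-binding futility boundaries: the critical value of
    the fixed single-stage exact binomial test is kept unadjusted while the
    interim boundary maximizes the probability of correctly stopping for
    futility subject to user bounds on power loss, on the probability of
    wrongly stopping, and on the interim timing.  Includes a scenario-grid
    comparison engine and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
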