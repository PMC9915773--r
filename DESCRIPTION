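Package: patchdep
Title: Sequential Patch Depletion Task: Simulation, Foraging Optimality, and
    Delay Discounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the sequential patch depletion operant procedure, in
    which a subject chooses between staying in a depleting reward patch and
    paying a changeover delay to reach a replenished one. Provides an
    event-level simulator of the task for arbitrary stay/leave policies,
    Marginal Value Theorem optimality benchmarks (cumulative rate of return,
    optimal leaving position and rejection volume), extraction of the
    standard dependent measures from event logs (reinforcement rate, patch
    changes, time in patch, rejection volume, percent deviation from
    optimality), hyperbolic delay-discounting fits with fixed bias and
    normalized area under the curve, composite scores with Pearson
    correlation matrices, and the Meng-Rosenthal-Rubin z-test for comparing
    dependent overlapping correlations. A synthetic-cohort generator with
    per-subject hyperbolic indifference thresholds makes the full pipeline
    runnable and testable end to end without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
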