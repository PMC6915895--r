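Package: allocsim
Title: Simulation of Subject-Allocation Procedures for Factorial Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing sequential subject-allocation procedures in
    two-level factorial experiments: simple randomization, stratified permuted
    blocks, maximum tolerated imbalance ("big stick"), minimal sufficient
    balance, and minimization by sum of ranges with random tie-breaking.
    Includes a synthetic-cohort generator with bootstrap resampling, balance
    and covariate-equivalence metrics, eligible-cell accounting, selection-bias
    guessing rules, and a Monte Carlo harness that aggregates results across
    simulated trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
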