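---
title: "Comparing allocation procedures for factorial trials by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing allocation procedures for factorial trials by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allocsim)
```

## The problem

A fully crossed factorial trial with four two-level intervention components
assigns each participant to one of $2^4 = 16$ cells. With a planned sample
of 304 the ideal cell size is 19, and even modest imbalance erodes power for
the factor main effects; at the same time the sixteen cells must stay
equivalent on the socio-demographic covariates that plausibly moderate
outcomes, and each assignment must stay hard to predict so that staff cannot
steer enrollment. No allocation procedure optimizes all three properties at
once. `allocsim` simulates candidate procedures on bootstrap cohorts so a
study team can see the trade-off in their own design before choosing.

The simulated experiment is: draw one source population; for each of
`n_sims` simulated trials, draw a bootstrap sample of `n_sample`
participants (with replacement, draw order = arrival order) and allocate it
sequentially with every candidate procedure, all procedures consuming the
identical cohort. Balance and equivalence are summarized per completed
trial; eligible-cell counts and correct-guess indicators are pooled over all
allocations.

## Procedures and their knobs

All procedures operate on the same running state: cell counts $n_c$,
per-cell covariate-positive counts $n_{ck}$, and (for blocked allocation)
per-stratum open blocks. Allocators are pure: they return a decision — the
eligible cell set, the chosen cell, a deterministic flag — and the harness
commits it. An allocation is *deterministic* exactly when one cell is
eligible.

- **Simple randomization** has no parameters and anchors the unpredictable
  end of the spectrum: its rule-1 guess rate must converge to $1/16$ and its
  rules 2–3 to $1/2$, which the test suite asserts.
- **Maximum tolerated imbalance** takes one integer, `mti_limit` (2 and 3
  are the limits compared here). The trigger is strict: free randomization
  continues while the cell-size range is at or below the limit and the big
  stick fires only once the range *exceeds* it, so the observed range can
  reach `mti_limit + 1` but never more. Checking the pre-assignment range
  (rather than a hypothetical post-assignment one) is the natural reading of
  a tolerated-imbalance trigger and is what the invariant tests pin down.
- **Stratified permuted blocks** takes the permitted block sizes (default
  16 and 32, each a multiple of the cell count) and the stratum definition
  (three strata: Hispanic; non-Hispanic Black; other — a participant
  positive on both indicators is Hispanic, following the coding order).
  Each time a stratum needs a block, its size is drawn uniformly from the
  permitted sizes, independently per stratum; nothing in the method fixes
  the mixing rule, so the uniform draw is declared here as this package's
  choice. The eligible-cell count is the number of *distinct* cells with
  remaining slots, which keeps it on the same 1–16 scale as the other
  procedures.
- **Minimal sufficient balance** takes `alpha_trigger` (default 0.30), the
  level of the per-covariate Pearson chi-square imbalance test run before
  every allocation. Two choices are worth making explicit. First, empty
  cells are excluded both from the test table and from lowest/highest-
  proportion candidacy: a 0/0 proportion is undefined and must neither
  attract nor repel votes. Second, when several cells tie at the extreme
  proportion, *all* of them receive the vote; this keeps the vote vector a
  deterministic function of state and participant, so randomness enters only
  at the final argmax tie-break. As `alpha_trigger` approaches 0 no test can
  fire and the procedure provably collapses to simple randomization (a
  property test).
- **Minimization** takes optional weights on the cell-size range and each
  covariate range, all defaulting to 1 (equal weighting; reweighting is a
  refinement the interface leaves open). With no informative covariates it
  degenerates to assign-to-smallest with random ties and keeps the range at
  most 1 — another tested invariant. The eligible set is the exact argmin
  set of the sum of ranges, verified in the suite against a brute-force
  oracle that rebuilds every hypothetical tally from the raw allocation
  history.

Equivalence at trial end uses the same chi-square statistic at
`equivalence_alpha = 0.05`. The level is not intrinsic to the procedures —
it is the conventional reading of "statistically significant" and is
exposed in the configuration. The test is Pearson's on the $2 \times K$
table over non-empty cells with $K-1$ degrees of freedom, without continuity
or small-sample correction: with ~19 participants per cell and binary
covariates, small expected counts are routine, and a correction-free
statistic keeps the MSB trigger behavior comparable across implementations.
Degenerate tables (covariate all-positive or all-negative, or fewer than two
non-empty cells) are "not testable" and count as non-significant. No
multiple-testing adjustment is applied: covariates are counted one by one,
which is what the per-covariate summary reports.

## Guessing rules

Three observers with full knowledge of the pre-allocation state (but not of
the allocator's random stream) guess each assignment before it is drawn:
rule 1 guesses a cell tied at the minimum count; rule 2 guesses the
factor-1 level with the smaller combined count; rule 3 gives each level a
point for the strictly smaller total and a point for the strictly smaller
number of Black-positive participants and guesses the level with more
points. "Smaller" is strict throughout and every tie — including a 0–0 or
1–1 point tie — resolves to a uniformly random guess; applying the same
random tie-resolution to all three rules keeps them comparable. Rule 3's
covariate criterion uses Black totals within factor-1 levels (not per-cell
quantities), the reading that matches a level-guessing observer.

## The synthetic generator

The generator emulates the *shape* of a realistic source dataset — a few
hundred participants from an urban pediatric clinic population with binary
socio-demographic covariates — not any particular dataset's joint
distribution. Ethnicity is drawn categorically with probabilities
$(0.40, 0.30, 0.30)$ for (Hispanic, non-Hispanic Black, other) and converted
to consistent Hispanic/Black indicators (exclusive by default; a
co-occurrence rate is available for stress-testing the stratum-precedence
rule); the six minimization covariates are independent Bernoulli at
prevalence 0.5. These defaults are invented, clearly configurable stand-ins:
no marginals were available to estimate, and 0.5 is the maximum-entropy
choice for an unconstrained binary covariate.

Consequently the simulated conditions reproduce the *data-free* quantities
of a 304-participant, 16-cell study sharply — simple-randomization balance
(a pure multinomial quantity), the MTI range and unpredictability profile,
chance-level guess rates — while quantities that depend on the covariate
joint distribution (the stratified-block and MSB equivalence profiles, the
minimization deterministic proportion) are matched only approximately.
Passing tests therefore show the procedures are implemented correctly and
behave as theory predicts under a neutral covariate distribution; they do
not certify performance on any particular real cohort, where correlated and
skewed covariates will shift the covariate-dependent summaries.

## Randomness and reproducibility

Every stream derives from one master seed through a labeled hash
(`derive_seed(master, "proc", procedure, sim)` and so on), giving each
procedure in each simulation its own named stream. Two consequences are
tested: the same master seed reproduces reports byte for byte, and adding or
removing a procedure from a run never changes another procedure's results.
Within one simulation the guessers' tie-break draws interleave with the
allocator's draws on that stream; the guesser still never *sees* the
allocator's upcoming draw, which is the property that matters.

## Numerical and reporting choices

Tallies are integers throughout; the sum-of-ranges update uses an $O(16)$
incremental range computation per candidate, verified against naive
recomputation. Argmin/argmax ties are never broken by index order — every
tie resolves by a uniform draw, because index-order tie-breaking would leak
predictability into exactly the procedures whose unpredictability is being
measured. CSV tables round percentages to one decimal; the eligible-count
distribution rows use largest-remainder rounding so each printed row sums to
exactly 100.0, while `report.json` keeps full precision.

## Problem sizes

The packaged study conditions are 250 simulations × 304 allocations per
procedure (76,000 allocations pooled per procedure), the scale at which the
summary tables stabilize: the Monte Carlo standard error of a pooled
proportion is about 0.17 percentage points, and of the mean cell-size range
about 0.05–0.15 participants. The full four-procedure run completes in
about a minute on one CPU; unit and property tests use smaller sequences
(100–300 allocations, a handful of simulations) where the property under
test does not need the full scale.

## Known limitations

- Only fully crossed two-level factorials with 1:1 allocation are supported;
  factors with more levels or unequal ratios are out of scope.
- MSB is implemented in its binary-covariate chi-square form; continuous
  covariates (t-test triggers) and biased-coin final probabilities are not
  included, nor are weighted-probability ("near-tie") minimization variants.
- The guessers are memoryless: convergence strategies that learn from past
  correct guesses, or that see the next participant's full covariate vector,
  would be strictly stronger adversaries than rules 1–3.
- The chi-square trigger treats the across-cell table jointly
  ($2 \times K$); pairwise-contrast formulations of MSB would trigger at
  different times.
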