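# allocsim

Monte Carlo comparison of subject-allocation procedures for two-level
factorial trials.

Multicomponent intervention trials built on factorial designs (here a
2×2×2×2 design, sixteen cells) face a three-way trade-off when assigning
participants to cells: **balance** of cell sample sizes, **equivalence** of
covariate distributions across cells, and **unpredictability** of the next
assignment. `allocsim` implements five sequential allocation procedures and a
simulation harness that quantifies all three properties for each, so a study
team can choose a procedure on evidence rather than precedent.

## Procedures

For a design with cells $c = 1,\dots,16$, running cell counts $n_c$ and
per-cell covariate-positive counts $n_{ck}$ for binary covariates
$k = 1,\dots,K$:

- **Simple randomization** (`sr`) — every cell always eligible, uniform
  choice.
- **Stratified permuted blocks** (`spb`) — within each of three
  race/ethnicity strata (1 Hispanic, 2 non-Hispanic Black, 3 other), consume
  randomly permuted blocks of 16 or 32 slots containing every cell equally
  often.
- **Maximum tolerated imbalance** (`mti2`, `mti3`, `mti:<L>`) — randomize
  uniformly while $\max_c n_c - \min_c n_c \le L$; once the range *exceeds*
  the limit, a "big stick" restricts eligibility to the smallest cells
  (random tie-break), so the range never exceeds $L+1$.
- **Minimal sufficient balance** (`msb`) — before each allocation, each
  covariate is tested for across-cell imbalance (Pearson chi-square over the
  non-empty cells, trigger level $\alpha = 0.30$). Each significant covariate
  casts votes: $+1$ to the lowest-proportion cells if the next participant is
  positive on it, $-1$ to the highest-proportion cells if negative. The
  participant goes to an argmax-vote cell (random tie-break); with no votes
  this is simple randomization.
- **Minimization** (`min`) — assign to the cell minimizing the sum of ranges

  $$S(c) = \mathrm{range}_{c'}\,\tilde n_{c'} + \sum_{k=1}^{K} \mathrm{range}_{c'}\,\tilde n_{c'k},$$

  where the tildes are the hypothetical tallies after placing the next
  participant in candidate cell $c$; ties are settled by simple random
  assignment (the random element).

Unpredictability is tracked as the eligible-cell count per allocation
(1 = deterministic, 16 = completely random) and as the success rates of three
guessing rules: guess the smallest cell (rule 1), guess the factor-1 level
with the smaller total (rule 2), or combine level size and Black-participant
counts (rule 3).

Because the kind of clinic dataset such simulations resample is typically not
shareable, the package includes a synthetic source-population generator
(default 332 participants, 2 stratification + 6 minimization binary
covariates) and draws bootstrap samples of 304 per simulated trial.

## Worked example

```r
library(allocsim)
cfg <- run_config(n_sims = 25, procedures = c("sr", "spb", "mti2", "min"),
                  seed = 2026)
report <- run_study(cfg)
print(report)
```

```
<allocation_report> 25 simulations x 304 participants, procedures: sr, spb, mti2, min

Cell-size balance (mean over simulations):
 procedure  min  max range
        sr 11.8 26.9  15.1
       spb 17.6 20.6   3.0
      mti2 18.0 20.9   2.9
       min 17.7 20.2   2.5

Unpredictability (pooled over allocations):
 procedure pct_deterministic pct_fully_random ave_cells guess1_pct guess2_pct
        sr               0.0            100.0      16.0        6.6       50.1
       spb               3.7             19.0      10.5       13.5       55.6
      mti2               5.9             48.4      10.5       19.4       56.1
       min              30.7              0.3       3.6       16.5       58.1
 guess3_pct
       49.9
       55.2
       54.6
       56.9

Covariate equivalence (avg % significant at trial end):
 procedure pct_sc pct_mc
        sr      8    5.3
       spb      0    8.0
      mti2      6    6.0
       min      0    0.0
```

Reading the output: simple randomization is fully unpredictable but spreads
cell sizes over a range of ~15 participants and regularly leaves covariates
significantly imbalanced. MTI with limit 2 caps the range near 3 while
keeping ~48% of allocations completely random. Minimization achieves the
tightest balance and leaves no minimization covariate significantly
different at trial end, at the cost of ~31% deterministic allocations — the
trade-off the simulation is designed to expose. `write_report(report, dir)`
emits the four summary tables as CSV plus a full-precision `report.json`.

A thin command-line front end is included:

```sh
Rscript inst/cli/allocsim.R generate-cohort --config cfg.json --out cohort.csv
Rscript inst/cli/allocsim.R run --config cfg.json --out results/ --n-sims 250
```

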