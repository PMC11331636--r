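# optifut

Exact two-stage design calculations for single-arm phase II trials with a
binary endpoint, and optimized **non-binding** futility boundaries.

## The problem

Single-arm phase II trials (typically oncology, with tumour response as the
endpoint) test

H0: p ≤ p0  versus  H1: p > p0

with an exact binomial test, where `p0` is the highest response rate at which
the treatment is uninteresting and `pa` the lowest rate warranting further
study. A two-stage design `(r1, n1, r, n)` evaluates `n1` patients first and
stops for futility if the number of responses `x1 ≤ r1`; otherwise `n − n1`
more patients are evaluated and H0 is rejected if the total responses
`x > r`. With `b(·, n, p)` and `B(·, n, p)` the binomial pmf and cdf, the
probability of rejecting H0 at true rate `p` is

P(reject | p) = Σ_{i = r1+1 .. n1} b(i, n1, p) · P(X2 > r − i),
  with P(X2 > r − i) = 1 − B(r − i, n − n1, p) (and = 1 when i > r),

the probability of early termination is PET(p) = B(r1, n1, p), and the
expected sample size is EN(p) = n1 + (1 − PET(p)) · (n − n1).

Simon's classical optimal design (minimal EN(p0)) often stops *wrongly* —
PET(pa) can approach 19% — and his minimax design (minimal n) often places
the interim after ~85% of patients, where stopping saves almost nothing.
Both use **binding** stopping rules: their critical values exploit the
mandatory stop, so ignoring the rule inflates the type I error. This package
implements, alongside Simon's and Kim's modified designs, an optimized
futility boundary that:

1. fixes `(n, r)` at the single-stage exact design (so the critical value is
   never adjusted and the type I error holds even if the rule is ignored —
   the boundary is valid as non-binding);
2. restricts the interim to `ratio_lower ≤ n1/n ≤ ratio_upper`
   (default 1/3–2/3), bounds the probability of wrongly stopping
   `PET(pa) ≤ π_wrong` (default 0.05) and the power loss
   `power ≥ 1 − β − Pow_loss` (default loss 0.05);
3. among all admissible `(r1, n1)`, maximizes the probability of *correctly*
   stopping for futility, PET(p0).

## Worked example

For `p0 = 0.25`, `pa = 0.40`, one-sided `α = 0.05`, `β = 0.20`:

```r
library(optifut)
pars <- design_params(0.25, 0.40, alpha = 0.05, beta = 0.20)
d <- optimized_futility_design(pars)
print(d)
#> Two-stage design (r1, n1, r, n) = (10, 39, 21, 62)
#>   stage 1: stop for futility if x1 <= 10 of 39
#>   stage 2: 23 further patients; reject H0 if x > 21 of 62
operating_characteristics(d, pars)
#>   n1/n = 0.63, n = 62
#>   PET(p0) = 0.620 (correct stop), PET(pa) = 0.045 (wrong stop)
#>   alpha_d = 0.0420, alpha_no_stop = 0.0428, power = 0.7979
#>   EN(p0) = 47.74, EN(pa) = 60.96
```

Reading: `(n, r) = (62, 21)` is exactly the single-stage exact binomial
design; the interim after 39 of 62 patients stops a truly futile treatment
with probability 0.620 while stopping a truly active one with probability
only 0.045; power drops from the single-stage 0.803 to 0.798, well within
the allowed loss of 0.05; and `alpha_no_stop = 0.0428 ≤ 0.05` shows the test
stays valid even if the trial ignores the stop. The same rule on the p-value
scale: stop when the interim one-sided exact p-value exceeds
`interim_pvalue_threshold(d, 0.25)` = 0.380.

The four comparator designs for the same scenario
(`simon_optimal`, `simon_minimax`, and `kim_modified` with
`variant = "optimal"` / `"minimax"`) return `(5, 20, 23, 71)`,
`(16, 51, 20, 60)`, `(6, 24, 22, 67)` and `(10, 40, 21, 62)`; interim
fractions 0.28, 0.85, 0.36, 0.65. `run_scenario_grid(scenario_grid())`
tabulates all five families over `p0 = 0.05 … 0.75` (`pa = p0 + 0.15`).

## Command line

```sh
Rscript exec/optifut optimized --p0 0.25 --pa 0.40 --alpha 0.05 --beta 0.20
Rscript exec/optifut grid --p0-from 0.05 --p0-to 0.75 --out grid.csv --format csv
Rscript exec/optifut verify --r1 10 --n1 39 --r 21 --n 62 --p 0.4 --simulate 100000 --seed 7
```

Subcommands: `single-stage`, `simon`, `kim`, `optimized`, `grid`, `verify`;
`--config FILE` reads flat `key: value` defaults which explicit flags
override. Exit status: 0 success, 2 argument error, 3 infeasible search.

The CSV written by `grid` has one row per (scenario, design family) with
columns `p0, pa, alpha, beta, design, r1, n1, r, n, ratio, pet_p0, pet_pa,
alpha_d, alpha_no_stop, power_d, en_p0, en_pa, status`.

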