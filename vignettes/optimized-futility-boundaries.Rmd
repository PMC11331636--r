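---
title: "Optimized non-binding futility boundaries for two-stage single-arm binomial trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimized non-binding futility boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optifut)
```

## The model

A single-arm phase II trial observes independent binary responses and tests
$H_0\colon p \le p_0$ against $H_1\colon p > p_0$ with the exact binomial
test. A two-stage design $(r_1, n_1, r, n)$ evaluates $n_1$ patients, stops
for futility if $x_1 \le r_1$, and otherwise continues to $n$ patients,
rejecting $H_0$ when the total response count satisfies $x > r$. Everything
this package computes reduces to binomial tail sums: with $b$ and $B$ the
binomial pmf and cdf, and $n_2 = n - n_1$,

$$
\Pr(\text{reject} \mid p) \;=\; \sum_{i=r_1+1}^{n_1} b(i, n_1, p)\,
\Pr(X_2 > r - i), \qquad
\Pr(X_2 > r - i) = 1 - B(r - i, n_2, p),
$$

where the stage-2 survivor probability equals 1 whenever $i > r$ (the
stage-1 count alone exceeds the critical value). The equivalent
"acceptance" form used for the attained level is

$$
\alpha^d \;=\; 1 - \Big[B(r_1, n_1, p_0) +
\sum_{i=r_1+1}^{\min(n_1, r)} b(i, n_1, p_0)\, B(r - i, n_2, p_0)\Big].
$$

A subtle point drove the implementation: a rejection-side sum truncated at
$\min(n_1, r)$ **omits** the certain-rejection outcomes $i > r$ whenever
$r < n_1$ — which happens in practice (the Simon minimax design for
$p_0 = 0.25$, $p_a = 0.40$ has $r = 20 < n_1 = 51$). `reject_probability()`
therefore carries the sum to $n_1$ with the survivor term saturating at 1;
`type1_error()` uses the acceptance form, which is already complete. The
test suite asserts their identity, and agreement with a brute-force
enumeration of the joint $(x_1, x_2)$ space, to $10^{-10}$ absolute.

Derived quantities: the probability of early termination
$\mathrm{PET}(p) = B(r_1, n_1, p)$ (a *correct* stop at $p_0$, a *wrong*
stop at $p_a$), the expected sample size
$\mathrm{EN}(p) = n_1 + (1 - \mathrm{PET}(p))(n - n_1)$, and the type I
error when the stopping rule is ignored,
$\alpha^d_{\text{no stop}} = 1 - B(r, n, p_0)$. Since ignoring a stop can
only add rejection events, $\alpha^d \le \alpha^d_{\text{no stop}}$ always.

## The design families

All searches share one feasibility notion: attained level
$\alpha^d \le \alpha$ and attained power $\ge 1 - \beta$ at $p_a$.

* **Single-stage** (`single_stage_design()`): smallest $n$ admitting an $r$
  with level $\le \alpha$ and power $\ge 1-\beta$; at that $n$, the smallest
  such $r$ (maximizing power).
* **Simon optimal / minimax** (`simon_optimal()`, `simon_minimax()`):
  exhaustive search over all feasible tuples with $n \le n_{\max}$,
  minimizing $\mathrm{EN}(p_0)$ or $n$ respectively.
* **Kim modified** (`kim_modified()`): the same objectives after two extra
  constraints, $\mathrm{PET}(p_a) \le 0.1$ and
  $1/3 \le n_1/n \le 2/3$ (both user-settable).
* **Optimized non-binding boundary** (`optimized_futility_design()`):
  $(n, r)$ are *frozen* at the single-stage values — the critical value is
  never adjusted for the interim look, which is exactly what makes the rule
  valid when treated as non-binding. Over all $(n_1, r_1)$ with
  $ratio_{lower} \le n_1/n \le ratio_{upper}$,
  $\mathrm{PET}(p_a) \le \pi_{wrong}$ and power
  $\ge 1 - \beta - Pow_{loss}$, the pair maximizing $\mathrm{PET}(p_0)$ is
  returned.

### Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| $\alpha$, $\beta$ | targeted one-sided error rates | 0.05, 0.20 | conventional phase II operating point |
| $\pi_{wrong}$ | max probability of wrongly stopping, $\mathrm{PET}(p_a)$ | 0.05 | a wrong stop kills a promising treatment; held to the level of a type-I-like risk |
| $Pow_{loss}$ | acceptable power loss versus the fixed design | 0.05 | the interim can only remove rejection probability; 0.05 keeps worst-case power at 0.75 |
| $ratio_{lower}, ratio_{upper}$ | interim timing window $n_1/n$ | 1/3, 2/3 | earlier: too little data to decide; later: stopping saves too little |
| Kim $\mathrm{PET}(p_a)$ bound | wrong-stop bound in the Kim variants | 0.1 | the looser control that family is defined with |
| $n_{\max}$ | search envelope for Simon/Kim | $\max(100, 2 n_{\text{single}})$ | contains all published designs for the default grid; user-overridable |

## Numerical choices

* All binomial quantities come from `stats::dbinom`/`stats::pbinom` (exact
  saddlepoint-free algorithms in double precision); nothing is approximated
  by normal or arcsine formulas.
* **Boundary slack.** Feasibility comparisons ($\le \alpha$,
  $\ge 1-\beta$, $\mathrm{PET} \le \pi_{wrong}$) carry an absolute slack of
  $10^{-12}$. Attained error rates can equal a bound *exactly* (e.g.
  $1 - B(0, 1, 0.05) = 0.05$), and without slack the decision would hinge
  on rounding direction. $10^{-12}$ is far below the spacing of attainable
  error rates between neighbouring tuples, so it cannot admit a genuinely
  infeasible design.
* **Interim-ratio test.** $ratio_{lower} \le n_1/n \le ratio_{upper}$ is
  inclusive and evaluated as $n_1 \ge ratio_{lower}\, n - 10^{-9}$ (and
  symmetrically above). At trial-scale denominators the nearest distinct
  rational is at least $1/(3n) \approx 10^{-3}$ away, so the tolerance only
  protects thirds that are not binary-representable.
* **Tie-breaking** (fixed, documented): Simon optimal — minimal
  $\mathrm{EN}(p_0)$, then $n$, $n_1$, $r_1$; Simon minimax — minimal $n$,
  then $\mathrm{EN}(p_0)$, $n_1$; optimized — maximal $\mathrm{PET}(p_0)$,
  then minimal $n_1$, then minimal $r_1$. For a fixed feasible
  $(r_1, n_1, n)$, the retained critical value $r$ is the smallest meeting
  the alpha constraint, which maximizes power; no selection objective
  depends on $r$ beyond feasibility.
* **Search internals.** For each $(n_1, n)$ pair the level and power of
  *every* $(r_1, r)$ combination are produced at once from two
  cumulative-sum matrices, so the default envelope ($n_{\max} = 124$ for
  the worked example) scans in seconds of pure R; results are cached per
  (parameters, $n_{\max}$) within the session. A deliberately literal
  tuple-by-tuple enumerator (`enumerate_feasible_designs()`) provides an
  independent route used by the certification tests.
* **Degenerate inputs.** $r_1 = n_1$ (always stop) is a valid
  `two_stage_design` with rejection probability 0 and
  $\mathrm{EN} = n_1$; converting it to the p-value scale warns, since no
  continuation outcome exists.

## The p-value form of the rule

Stopping rules are often communicated as "stop if the interim p-value
exceeds $\alpha_0$". The package defines the interim p-value as the
one-sided **upper-tail** exact binomial p-value
$P(X_1 \ge x_1 \mid p_0) = 1 - B(x_1 - 1, n_1, p_0)$ — a documented
convention choice; with it, `interim_pvalue_threshold()` returns
$\alpha_0 = 1 - B(r_1, n_1, p_0)$, the p-value of the smallest continuing
outcome, and the count rule $x_1 \le r_1$ and the threshold rule
$p_{\text{interim}} > \alpha_0$ agree for every possible $x_1$ (the tests
check this exhaustively).

## Genuinely open choices made here

* **"No futility stop" is not $r_1 = -1$.** Every compared family has an
  interim rule; the single-stage evaluation is a separate entity rather
  than a degenerate tuple, keeping the tuple invariants simple.
* **Comparison rows.** The comparison table carries the five two-stage
  families; the single-stage design is available as an opt-in family whose
  row holds the fixed-design characteristics with `r1 = n1 = NA`.
* **Kim reading.** Exactly the two constraints named above are applied
  before Simon's objectives. The original publication mentions further
  constraints; they are out of scope here, and the implemented reading
  reproduces the published modified tuples for the reference scenario.
* **Feasibility below the single-stage $n$.** No lower bound on $n$ is
  imposed in the enumeration: a two-stage design can be feasible with
  *fewer* total patients than the single-stage minimum (the reference
  scenario's minimax design needs 60 versus 62), because enforcing the
  interim stop changes the attained error rates.

## What the tests establish — and what they do not

There is no synthetic-data generator in this package: every verified
quantity is an exact finite binomial sum, so tests compare implementations
against independent re-computations (brute-force joint enumeration, exact
rational arithmetic for a cdf value, a $10^6$-replicate Monte-Carlo check of
an expected sample size, and exhaustive certification of each search
objective on reduced problems with $n_{\max} \le 40$). A green suite
establishes that the arithmetic and the search logic are correct *given the
model* — independent Bernoulli responses with a constant true rate and
analysis exactly at $n_1$. It says nothing about drift in response rates,
over-running patients between interim and decision, or operational biases
of real interim analyses.

## Known limitations

* Exactly two stages; no efficacy (superiority) stopping; no designs with
  more than one interim look.
* No randomized decision rules to exhaust $\alpha$ exactly, and no
  admissible-design frontier between the optimal and minimax corners.
* Inference after a non-binding stop (adjusted confidence intervals) is out
  of scope.
* Searches are exhaustive; for $n_{\max}$ beyond a few hundred the scan
  time grows roughly with $n_{\max}^4$.
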