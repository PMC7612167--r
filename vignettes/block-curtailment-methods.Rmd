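---
title: "Exact design of stochastically curtailed block-randomised two-arm trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact design of stochastically curtailed block-randomised two-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scblock)
```

## The design problem

Phase II oncology trials with a binary response endpoint are frequently
single-arm because randomised two-arm trials need substantially more
participants. `scblock` implements a two-arm design that narrows that gap:
participants are allocated in randomised blocks of $2B$ ($B$ per arm, so
the arms are balanced at every analysis), and after each complete block
the accumulating data may stop the trial early — either because the final
conclusion is already certain (non-stochastic curtailment, NSC) or because
it is nearly certain (stochastic curtailment, SC).

With anticipated response rates $p_0$ (control) and $p_1$ (treatment), the
null hypothesis is $H_0: p_T \le p_C$, to be tested with type I error at
most $\alpha$ under $p_C = p_T = p_0$ and power at least $1-\beta$ under
$(p_C, p_T) = (p_0, p_1)$. The test statistic is the difference in
responses $X_T(m) - X_C(m)$ after $m$ participants per arm. It is
convenient to count *successes* — a response on treatment or a
non-response on control:
$$S(m) = X_T(m) + m - X_C(m), \qquad S(m) \in \{0, \dots, 2m\}.$$
$S$ is non-decreasing as the trial proceeds, which is what makes exact
curtailment bounds simple.

**Boundary convention.** A design realisation is written
$(r, N, B, \theta_F, \theta_E)$; $N$ is the maximum total sample size
(both arms) and $r$ the final stopping boundary. In this package the null
is rejected when the final difference *exceeds* $r$:
$X_T(N/2) - X_C(N/2) \ge r + 1$, equivalently $S(N/2) \ge N/2 + r + 1$.
(Published design tables for this family of designs — including the
two-stage randomised comparator — tabulate $r$ under this convention; the
package reproduces those tables exactly, which pins the inequality.)
Consequently, at any earlier block end,

* a **go** decision is certain when $S(m) \ge N/2 + r + 1$ (successes
  cannot decrease);
* a **no-go** decision is certain when $2m - S(m) \ge N/2 - r$ (even an
  all-success future cannot push the final difference past $r$).

## Conditional power and the backward recursion

The conditional power $CP(S, m)$ is the probability of ultimately
rejecting $H_0$ given the current state, always computed at the
anticipated rates $(p_0, p_1)$ — there is no re-estimation of response
rates mid-trial. One block contributes $i \in \{0, \dots, 2B\}$ successes
with probability
$$P(i, B \mid p_C, p_T) = \Pr\{X_T(B) + B - X_C(B) = i\},$$
the convolution of $\mathrm{Binom}(B, p_T)$ and
$\mathrm{Binom}(B, 1 - p_C)$ (`block_success_pmf()`). Starting from the
final analysis, where $CP$ is the 0/1 indicator of rejection, the table is
filled backwards: at an interior state that is neither go- nor
no-go-certain,
$$D = \sum_{i=0}^{2B} P(i, B \mid p_0, p_1)\, CP(S + i,\, m + B).$$

Under NSC (`cp_table_nsc()`) the interior value is kept as $D$. Under SC
(`cp_table_sc()`) two thresholds $0 \le \theta_F < \theta_E \le 1$ round
it: $D < \theta_F$ becomes 0 (stop, no-go), $D > \theta_E$ becomes 1
(stop, go), and $\theta_F \le D \le \theta_E$ is retained as a continue
state. The rounding is applied *during* the backward pass, so rounded
values feed the sums of earlier blocks; the resulting table is the exact
law of the curtailed trial, not an approximation to it.

Three numerical choices matter and are deliberate:

* **Strict comparisons, no epsilon.** Thresholds are compared with
  strict `<`/`>`; equality continues. This is safe because thresholds are
  drawn from the attainable conditional-power grid itself (the search uses
  the NSC table's interior values as candidates), so search and evaluation
  classify states identically, bit for bit.
* **Certainty by mask, not by accumulation.** Go/no-go-certain states are
  set to exact 0/1 doubles rather than left to sums that merely approach
  them, so the decision classification (`cp == 0`, `cp == 1`) is exact.
* **Threshold snapping.** Published tables print $\theta_F, \theta_E$ to
  3–4 decimals. A rounded threshold can misclassify the handful of states
  whose conditional power lies between the printed and the exact value,
  which visibly shifts the operating characteristics.  `block_design(...,
  snap = TRUE)` snaps a printed threshold to the nearest attainable
  interior NSC value; within the printed rounding window that value is
  unique in every case we checked.

## Operating characteristics by forward recursion

`reach_probabilities()` runs the complementary forward pass under any true
rates $(p_C, p_T)$: mass starts at the first block end with the block
distribution, propagates only through *continue* states (stop states
absorb), and yields the first-passage probability of every state — so
stopped sample paths are counted exactly once. From it,
`operating_characteristics()` assembles
$$ESS(p_C, p_T) = \sum_{\text{stop states}} 2m \cdot
  \Pr\{\text{first passage}\},$$
the rejection probability (total first-passage mass into go states),
$\alpha^*$ and power (evaluations at $(p_0,p_0)$ and $(p_0,p_1)$), the
stopping-point distribution, and the smallest attainable stopping size
(computed structurally from the table: the earliest block end where a
chain of continue states can reach a stop state). ESS is reported in
participants on both arms; printed tables round to one decimal, half-up,
and the package does the same *for display only*.

```{r}
d <- block_design(r = 5, n = 116, block = 1,
                  theta_f = 0.1348, theta_e = 0.9831,
                  p0 = 0.3, p1 = 0.5, snap = TRUE)
operating_characteristics(d)
```

## Searching for admissible designs

A realisation is *feasible* when $\alpha^* \le \alpha$ and power
$\ge 1-\beta$; it is *dominated* when another realisation is no worse on
all of $ESS(p_0,p_0)$, $ESS(p_0,p_1)$ and $N$ and strictly better on one;
feasible and non-dominated realisations are *admissible*.
`find_admissible()` enumerates $(r, N)$, draws candidate
$(\theta_F, \theta_E)$ pairs, evaluates every curtailed design exactly,
and Pareto-filters the feasible results, labelling the
$p_0$-/$p_1$-optimal and minimax members.

The candidate thresholds are the *trial-specific* conditional-power
values: operating characteristics only change when a threshold crosses an
attainable $CP$ value, so the grid is the set of interior NSC values
pooled over all block ends, subject to $\theta_F \le \theta_{F max}$
(default $p_1$), $\theta_E \ge \theta_{E min}$ (default 0.7) and
$\theta_F < \theta_E$. When the pair count exceeds `max_combos` (default
$10^6$), the sorted values are thinned by deleting every other one until
it fits. Two design choices here were genuinely open:

* Candidates are pooled across all block ends (per-$m$ pooling cannot be
  distinguished from the published threshold values without re-running the
  original full search).
* Candidates come from the *NSC* table of the same $(r, N, B)$;
  recomputing them self-consistently under each SC design would be
  circular.

The grid evaluation is the package's only compiled code (Rcpp): a full
per-$(r,N)$ grid at $N = 116$ is roughly $6\times10^5$ pairs and evaluates
in under half a minute, where the pure-R recursion would take the better
part of an hour. The C++ path mirrors the R recursion's accumulation
order exactly and is equality-tested against it; the R implementation
remains the reference for single designs. Halving the grid is *not*
innocuous: a heavily thinned grid keeps feasible designs but loses the
best ones by several participants of ESS, which is why the package test
that recovers the published optimum fixes $N$ and $r$ at their published
values and runs the full grid rather than shrinking it.
A complete search over all $(r, N)$ up to $N = 120$ remains an
hours-of-CPU undertaking and is deliberately out of the test suite;
`search_config(n_values = , r_range = , max_combos = )` are the scale
knobs.

## Comparator designs

Four published designs serve as benchmarks, all evaluated exactly
(`simon_eval`, `jung_eval`, `carsten_eval`, `chen_eval`); the curtailed
two were originally tabulated from 10,000-replicate simulations, so
agreement with their published rows is expected only within Monte-Carlo
error (±3 SE ≈ ±1 participant on ESS), while the package's own values are
exact dynamic programmes. `comparator_simulate()` reproduces the
simulation protocol as a cross-check, and `comparator_admissible()` runs
the same feasibility/dominance machinery over their parameter spaces.

The source tables do not restate the boundary inequality conventions of
these designs, so they were *calibrated*: the convention reproducing the
published expected sample sizes was frozen and is asserted by the test
suite.

* **Simon (single-arm)**: stop at stage 1 iff responses $\le r_1$; reject
  iff total responses $> r$. Exact binomial two-stage formulas.
* **Jung (randomised two-stage)**: continue iff the interim difference
  *exceeds* $r_1$; reject iff the final difference *reaches* $r$. This
  pair reproduces both published rows at $(0.3, 0.5)$ exactly at both rate
  pairs; either inequality flipped fails. Negative $r_1$ is allowed
  (a published row uses $r_1 = -1$).
* **Carsten & Chen (paired successes)**: a pair is a success iff the
  treatment member responds and the control member does not
  ($p_s = p_T(1-p_C)$); monitored after every pair; go at exactly $r$
  successes; no-go as soon as $r_1$ by pair $n_1$, or $r$ overall, is
  unreachable. Interim continuation requires *reaching* $r_1$
  ($s \ge r_1$).
* **Chen et al. (per-patient differences)**: allocation alternates
  T, C, T, C, …; success is a treatment response or control non-response,
  so the success probability alternates between $p_T$ and $1-p_C$; go as
  soon as the final difference $\ge r$ is guaranteed, no-go as soon as it
  — or the interim requirement $X_T - X_C \ge r_1$ after $n_1$ *per arm*
  — is unreachable. The per-arm interim placement is itself a calibration
  result: with the interim after $n_1$ patients total, the published
  $p_0$-optimal row is missed by some twenty participants; per-arm, all
  four published values at $(0.3, 0.5)$ agree within 0.12.

One published comparator set resists reproduction: the Jung rows of the
high-response-rate example ($p_0 = 0.7$) are off by up to eleven
participants under every convention combination tried, while the
$(0.3, 0.5)$ rows are exact. The package documents this as a discrepancy
rather than fitting a bespoke convention to one table.

## Loss functions and misspecification

`loss_score()` computes
$L = w_0\,ESS(p_0,p_0) + w_1\,ESS(p_0,p_1) + (1-w_0-w_1)\,N$ and
`omni_admissible_map()` sweeps the weight simplex (default grid step 0.01,
5151 points — the published analyses do not state their grid), recording
at each point the approach whose best admissible realisation minimises
$L$; ties are reported jointly and split equally in the area fractions,
which are grid-point fractions, not measure-theoretic areas.

`rejection_surface()` evaluates a *fixed* design — boundaries built at the
anticipated rates — over a grid of true rates (default step 0.1). This
quantifies sensitivity to misspecification: the exact surface for the
block design is markedly flatter near the null diagonal than the
paired-success comparator's, whose rejection probability at equal true
rates can be several times its nominal level. The surface's diagonal cell
at $(p_0, p_0)$ is exactly $\alpha^*$ and its $(p_0, p_1)$ cell exactly
the power, which the tests assert.

## The simulator, and what the tests do and do not show

`simulate_trial()` / `estimate_chars()` draw block outcomes
$X_T(B) \sim \mathrm{Binom}(B, p_T)$, $X_C(B) \sim \mathrm{Binom}(B, p_C)$
and apply the precomputed table after each block. The simulator is an
*oracle*, never an estimator: every exact quantity in the package is
checked against it (and, for tiny designs, against exhaustive enumeration
of all per-block outcome sequences, which is exact to machine precision).
Replicates advance a single seeded RNG stream, drawn vectorised over the
trials still running; results are reproducible for a given
`(seed, nreps)`.

The generator emulates exactly what the design model assumes: independent
Bernoulli responses at fixed rates, balanced blocks, decisions only at
block ends. Real trials depart from this in ways the model does not
represent — accrual in time, response lag, within-block imbalance from
stratification, drifting response rates — so passing tests certify the
*computations* under the stated model, not robustness to those
departures (the misspecification surface covers rate misspecification
only).

## Problem sizes used in the test suite

Exhaustive-enumeration oracles run at $N \le 12$, $B = 1$ (at most
$4^6$ outcome paths per evaluation). Monte-Carlo consistency checks use
$10^5$ replicates per published design realisation, and comparator
cross-checks $10^4$ (the published estimation size). The
published-optimum recovery search fixes $(r, N) = (5, 116)$ with the full
candidate grid (~$6\times10^5$ pairs). These sizes were chosen as the
smallest that still separate a correct implementation from a subtly wrong
one at the tolerances used.

## Known limitations

* Stopping only at block ends; within-block (per-patient) states are never
  represented. Variable or mixed block sizes and mid-trial boundary
  re-estimation are out of scope.
* Equal 1:1 allocation only; no response-adaptive randomisation.
* No inference after stopping (bias-adjusted estimators, confidence
  intervals); the package computes design operating characteristics only.
* The type I error guarantee is at the anticipated null rate $p_0$;
  controlling it over all $p_C = p_T$ requires designing at $p_0 = 0.5$,
  which may not reflect prior belief.
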