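# scblock

Exact design and evaluation of **stochastically curtailed,
block-randomised two-arm phase II trials** with a binary outcome.

## The problem

Randomised two-arm trials are the gold standard, but in phase II oncology
they are often passed over for single-arm designs because they need many
more participants. One way back is aggressive early stopping: let the
trial end not only when its final conclusion is already *certain*
(non-stochastic curtailment), but also when it is *nearly* certain
(stochastic curtailment, SC). `scblock` implements a design that does this
within randomised blocks of `2B` participants (`B` per arm), so the arms
are balanced at every look and the number of interim analyses is under the
investigator's control — from two looks to near-continuous monitoring.

For anticipated control/treatment response rates `p0 < p1`, the design
tests `H0: pT <= pC` with the response-difference statistic
`XT(m) − XC(m)`. Counting a *success* as a treatment response or a control
non-response, `S(m) = XT(m) + m − XC(m)`, a realisation
`(r, N, B, θF, θE)` works as follows. At the final analysis the null is
rejected iff the difference **exceeds** `r`. After every earlier block,
the **conditional power** — the probability of eventual rejection, always
computed at `(p0, p1)` — follows the backward recursion

    CP(S, m) = Σ_i P(i, B | p0, p1) · CP(S + i, m + B)

over the distribution of block successes (a convolution of
`Binom(B, p1)` and `Binom(B, 1 − p0)`), with interior values rounded down
to 0 when `CP < θF` (stop, futility) and up to 1 when `CP > θE` (stop,
efficacy), the rounding feeding back into earlier blocks. The resulting
table is the *exact* law of the curtailed trial: type I error, power,
expected sample size (ESS) and the whole stopping-time distribution come
from a forward first-passage recursion, with no simulation error.

The package also provides:

* an **admissible-design search** (`find_admissible()`) over
  `(r, N, θF, θE)` with candidate thresholds drawn from each design's own
  attainable conditional-power grid, feasibility filtering
  (`α* ≤ α`, power `≥ 1 − β`) and Pareto dominance removal, with the
  threshold grid evaluated in compiled code;
* exact evaluation of four **comparator designs** — Simon's single-arm
  two-stage, Jung's randomised two-stage, the Carsten & Chen curtailed
  paired-success design and the Chen et al. per-patient curtailed design;
* **loss-score comparison** `L = w0·ESS(p0,p0) + w1·ESS(p0,p1) +
  (1−w0−w1)·N` across approaches over the weight simplex
  (`omni_admissible_map()`);
* **misspecification surfaces** (`rejection_surface()`): the exact
  rejection probability of a fixed design under true rates that differ
  from the anticipated ones;
* a seeded **simulator** (`simulate_trial()`, `estimate_chars()`) used
  purely as an independent check on the exact computations;
* a thin **command line** (`inst/cli/scblock`) with `search`, `evaluate`,
  `compare`, `misspec` and `simulate` subcommands driven by YAML/JSON
  configs and CSV/JSON tables.

## Worked example

The `p0`-optimal block-size-two realisation for
`(α, β, p0, p1) = (0.15, 0.20, 0.30, 0.50)`. Published thresholds are
printed rounded; `snap = TRUE` restores the exact attainable
conditional-power values they were rounded from:

```r
library(scblock)
d <- block_design(r = 5, n = 116, block = 1,
                  theta_f = 0.1348, theta_e = 0.9831,
                  p0 = 0.3, p1 = 0.5, snap = TRUE)
d
#> Stochastically curtailed block-randomised two-arm design
#>   r = 5, N = 116 (58 per arm), block = 1 per arm (58 analyses)
#>   CP thresholds: theta_f = 0.134842, theta_e = 0.983141
#>   anticipated rates (p0, p1) = (0.3, 0.5); alpha = 0.15, beta = 0.2

operating_characteristics(d)
#> Exact operating characteristics
#>   alpha* = 0.1478, power = 0.8001
#>   ESS(p0,p0) = 47.3, ESS(p0,p1) = 47.2, max N = 116, min stop = 8
```

The design respects both error constraints and, despite randomising 116
participants at most, is *expected* to stop after about 47 under either
hypothesis — much closer to a single-arm trial than to a fixed two-arm
design with the same guarantees. `min stop = 8` is the earliest the trial can possibly end.
The boundaries themselves live in the conditional-power table:

```r
head(as.data.frame(cp_table_sc(d)), 4)
#>   m S        cp decision
#> 1 1 0 0.6666221 continue
#> 2 1 1 0.7884176 continue
#> 3 1 2 0.8739935 continue
#> 4 2 0 0.4703897 continue
```

Sensitivity to misspecified rates, exactly:

```r
d4 <- block_design(r = 3, n = 62, theta_f = 0.128, theta_e = 0.932,
                   p0 = 0.1, p1 = 0.3, snap = TRUE)
rejection_surface(d4, p_grid = c(0.2, 0.3))["0.3", "0.3"]
#> [1] 0.3450197
```

— i.e. if both true rates are 0.3 rather than the anticipated
`(0.1, 0.3)`, this design rejects with probability 0.35; comparing such
surfaces across design approaches (`rejection_surface()` accepts the
comparator designs too) is the relevant check when `p0` may be
underestimated.

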