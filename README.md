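# agglomatch

Agglomerative matching for causal inference on land-tenure territories.

## The problem

How much long-term forest restoration does a land-tenure regime cause?
Comparing, say, Indigenous lands against private properties by statistical
matching runs into a structural obstacle: treatment territories are few and
large (hundreds to tens of thousands of hectares), while the candidate
controls are millions of small private properties.  One-to-one matching
either drops most treatment units for lack of a comparable control or
matches them badly.

`agglomatch` implements **agglomerative matching**: for each treatment
territory *t*, a synthetic control *C* (an *agglomerate*) is grown by
greedily merging candidate control territories.  Unlike synthetic-control
averaging, merging mirrors how territories compose physically — *summable*
covariates (area, outcome totals) are **summed**, the remaining covariates
(climate, topography, accessibility) are **area-weighted averaged**:

```
summable:       v(C*) = v(C) + v(c)
non-summable:   x(C*) = (A_C x_C + A_c x_c) / (A_C + A_c)
```

At each step the candidate `c` minimizing the L2 distance between the
standardized covariates of `C*` and `t` is merged; the loop stops when the
agglomerate's area exceeds the target's (the overshooting merge is kept) or
no merge strictly decreases the distance.  Candidates come from an
approximate nearest-neighbour index (a random-projection-tree forest) over
the control pool's non-summable covariates; because the index is stochastic,
the construction is repeated under derived seeds and the run with the
smallest worst-covariate |SMD| (the **mini-max** run) is selected.

Downstream, treated units and their agglomerates are re-matched by **optimal
full matching** (minimum-cost network flow), and the ATT is estimated
**doubly robustly**: weighted least squares of the outcome on the treatment
indicator and all ten covariates over the matched sample, g-computation for
the average treatment effect on the treated, and cluster-robust (CR1)
standard errors over the matching strata with a t(G−1) reference.

A **trajectory** module derives the outcome variables from annual
forest/non-forest masks: long-term restoration gains (regrowth after ≥3
years of non-forest, persisting ≥10 years and through the final observed
year), restoration reversals (3–10 years of regrowth, then cleared), with a
minimum-mapping-unit filter (components of <11 connected pixels removed)
and per-territory aggregation to hectares.  A **synthetic-data** module
generates both territory tables and mask landscapes with known ground
truth, so the whole pipeline is testable without any external data.

## Worked example

```r
library(agglomatch)

gen  <- generate_territories(synthetic_config(seed = 1))   # 30 treated, 2000 controls
tr   <- subset(gen$territories, role == "treatment")
co   <- subset(gen$territories, role == "control")

cfg     <- match_config(K = 500, n_runs = 20, seed = 1)
sets    <- repeat_matching(tr, co, config = cfg)
reports <- lapply(sets, balance_report, treatments = tr, controls = co)
sel     <- select_minimax(reports)
chosen  <- sets[[sel$chosen_run_id]]
print(reports[[sel$chosen_run_id]])
estimate_att(chosen, tr, "gain_ha", config = cfg)
```

prints (abridged):

```
Balance report, run 9 - max |SMD| = 0.06401
      covariate smd_unmatched smd_matched
        area_ha        2.3456     0.04622
 forest1985_pct        0.1095     0.06088
    ...
    dist_rivers        0.2472     0.06401
    pop_density       -0.0862    -0.03259
ATT (gain_ha, agglomerate_OFM): 12.641 ha  [SE 4.6, p = 0.0102]  n_treated = 30
```

Reading: before matching the treated group is grossly incomparable (area
|SMD| 2.35); after agglomeration every covariate sits within the ±0.1
balance convention (the mini-max run's worst is 0.064).  The doubly-robust
ATT estimate for long-term gains is 12.6 ha per treated territory (true
injected effect in this synthetic draw: 10 ha), with a 4.6 ha
cluster-robust SE — the effect is detected (p ≈ 0.01) and the truth lies
well within ±2 SE.

The same pipeline runs from the command line via
`inst/cli/agglomatch.R` (subcommands `simulate-territories`,
`simulate-landscape`, `classify`, `match`), writing balance, run and
results CSVs plus a `manifest.yaml` that reproduces the run bit-for-bit.

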