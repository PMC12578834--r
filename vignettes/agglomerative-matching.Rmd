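---
title: "Agglomerative matching: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agglomerative matching: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agglomatch)
```

## The estimation problem

We want the average treatment effect on the treated (ATT) of a land-tenure
regime on two territory-level outcomes measured in hectares: long-term
restoration gains and restoration reversals.  Treatment territories
(Indigenous lands, agrarian-reform settlements, Quilombola territories,
protected areas) are few, large, and systematically placed on different
land than the control pool of private properties, which is enormous but
made of much smaller units.  Classical matching must either drop treated
units without close controls — unacceptable when the treated sample is the
estimand — or accept severe covariate imbalance.

Agglomerative matching sidesteps the size mismatch by *building* each
treated unit's control.  Because territory outcomes and areas are totals,
a union of control territories is itself a meaningful territory-like unit:
its area and outcome totals are the sums over members, and any
per-territory mean covariate (temperature, slope, distance to roads, ...)
is the area-weighted average.  This additivity is what distinguishes the
method from synthetic-control weighting: members are merged whole, not
blended.

## The greedy construction

For one treated unit $t$ with candidate list $\mathcal{K}$:

1. start with an empty agglomerate $C$;
2. for every remaining candidate $c$, form the provisional merge $C^*$
   (summables summed, non-summables area-weighted);
3. accept the candidate minimizing
   $\lVert z(C^*) - z(t) \rVert_2$, where $z(\cdot)$ standardizes all ten
   covariates, area included, by a frozen scaler;
4. stop when (a) the accepted merge pushes the agglomerate's area past
   $t$'s (that merge is kept), (b) no candidate strictly decreases the
   distance, or (c) candidates run out.

The first merge is unconditional — the empty agglomerate has no distance,
so the closest single candidate seeds $C$.  Exact distance ties break
toward the lowest territory id, which makes runs reproducible.  The trace
of accepted distances is strictly decreasing up to the stop step, a
property the test suite asserts and the exhaustive-search oracle bounds
from below.

Candidate lists come from an approximate nearest-neighbour index over the
*non-summable* covariates only (a partially built agglomerate's area says
nothing about which controls are environmentally similar).  With no ANN
library available as a dependency, the package implements the classical
random-projection-tree forest: each tree splits the pool recursively by
hyperplanes through the midpoint of two random points; queries descend the
forest best-first by hyperplane margin, collect ~2K leaf candidates and
re-rank them exactly.  The forest is rebuilt per run under a derived seed;
this is the stochastic component that repeated runs quantify.

### Standardization reference

The scaler is frozen before matching.  The package standardizes by the
*treated-group* moments (the same ATT convention used for SMD
denominators), not the pooled sample.  The pooled alternative (available
via `match_config(standardization = "pooled")`) breaks down whenever the
treated group is a non-trivial fraction of the sample: its much larger
areas inflate the pooled area SD nearly an order of magnitude, the greedy
objective then rewards closing a multi-SD area gap almost exclusively, and
candidates are chosen by size rather than by environment, leaving
substantially worse covariate balance at desk scale.

### What the greedy loop cannot do

The algorithm is myopic.  Two failure modes are visible at desk scale and
are left as-is because they are properties of the method, not bugs: the
final merge typically overshoots the target's area by about half a member,
and occasionally the loop stops early with an area deficit because every
remaining merge would disturb the already-matched covariates more than the
area gain is worth (with a small agglomerate, each merge's weight
$a_c/(A_C+a_c)$ is large).  Optimal full matching and the outcome
regression absorb most of the residual.

## Balance, mini-max selection, prognostic scores

Balance is reported as standardized mean differences
$(\bar{x}_T - \bar{x}_C)/s_T$, with $s_T$ the treated-group SD from the
*unmatched* sample, so matched and unmatched SMDs share a denominator.
|SMD| ≤ 0.1 is the conventional adequacy threshold.  Across the repeated
stochastic runs the package selects the run with the smallest maximum
absolute SMD (mini-max), ties to the lowest run id.  As a complementary
one-number diagnostic, the prognostic score is the prediction of a
control-pool-only OLS of the outcome on the ten covariates; its SMD
summarizes imbalance in the outcome-relevant direction.  Distribution
exports (eCDF, eQQ, kernel density) are plain tables; plotting is left to
the user.

The run-to-run spread of matched SMDs is small relative to their
systematic component (the candidate lists shrink each covariate part-way
toward the pool mean), so mini-max selection trims the tail rather than
transforming the distribution; the package also reports the mean ATT
across runs next to the chosen run's ATT (`att_stability()`) to show the
result is not idiosyncratic to one seed.

## Optimal full matching

Re-matching treated units to agglomerates uses optimal full matching:
a partition into strata, each holding one treated with ≥1 controls or one
control with ≥1 treated, minimizing the total of within-stratum
treated–control distances on the standardized covariates.  That objective
is exactly the minimum-weight edge cover of the bipartite distance matrix,
solved here by the textbook reduction: subtract each unit's cheapest-edge
cost, find a minimum-cost matching on the reduced costs by
successive-shortest-path min-cost flow (augmenting only while a path has
negative cost), then attach every still-uncovered unit through its
cheapest edge; redundant edges (possible only under ties) are pruned so
every component is a star.  Exactness is verified against a brute-force
enumeration of all star forests on instances up to 4×4.  ATT weights are
standard: treated 1, controls $n_T/n_C$ within their stratum.  Optional
common-support trimming discards controls outside the treated group's
per-covariate standardized range before matching.

## Doubly-robust estimation

On the matched sample (treated units and agglomerates, full-matching
weights) the package fits WLS of the outcome on the treatment indicator
plus all ten covariates, and reports the g-computation ATT: the average,
over treated units, of the fitted difference between treatment and
control at their observed covariates (equal to the treatment coefficient
in this additive model).  Matching supplies the design robustness,
the regression the model robustness; no propensity term is used.

Variance is the cluster-aggregated sandwich over matching strata.  The
default is CR1 (the $G/(G-1)\cdot(n-1)/(n-k)$ degrees-of-freedom
correction) with a two-sided $t_{G-1}$ reference.  The uncorrected CR0
with a normal reference — also available — measurably over-rejects at the
few-dozen-cluster counts a matched sample produces; the test suite checks
that CR1 with $t_{G-1}$ keeps the empirical 5%-level size of the null test
within [0.03, 0.07] over 500 replicates and 2-SE recovery of an injected
10 ha effect at 95% or better over 100 seeds.  Any residual hint of
anti-conservatism at ~30 clusters is a known limitation of first-order
cluster corrections, not specific to this pipeline.

## Trajectory classification

Annual forest/non-forest masks are reduced to per-pixel regrowth episodes
(maximal runs of consecutive forest years).  An episode is restoration
only if preceded by ≥3 consecutive non-forest years and persisting ≥3
years; restoration persisting ≥10 years and through the final observed
year is a long-term gain; persisting 3–10 years (10 inclusive) and then
cleared is a reversal; persisting >10 years but later cleared is excluded
(mature-forest loss, a legally distinct event); persisting to the final
year but <10 years old is too recent to classify.  Forest present in the
first observed year has no observable prior non-forest window and is
baseline forest, never restoration.  Each episode of a pixel is classified
independently, so one pixel can contribute a reversal and a later gain.

Components of fewer than 11 connected pixels are removed per category.
Connectivity defaults to 8 (queen), the common remote-sensing choice, and
is configurable to 4.  Components are computed within cohorts sharing the
episode start year, so unrelated events that touch spatially are not
welded into one component — the grouping choice is documented here because
annual-cohort versus joint filtering is genuinely open; joint filtering is
available via `group_by_start_year = FALSE`.  Counts convert to hectares
at 0.09 ha per 30 m pixel (configurable), and aggregation ignores pixels
outside any territory.

## The synthetic testbed

`generate_territories()` emulates the structural regime the method is for:
30 treatment territories (lognormal areas, median 2,000 ha) over 2,000
controls (median 100 ha, narrow dispersion so *every* control is small
relative to a target and agglomeration is genuinely forced, ~20 members
per agglomerate).  Nine environmental covariates are drawn from a
correlated Gaussian model with realistic units; treated means are shifted
by 0.08–0.25 control-SDs toward a "remoter, steeper, wetter" profile,
calibrated so the pre-matching max |SMD| sits clearly above the 0.1
threshold (~0.2–0.3 on covariates, ~2 on area) and matching has real work
to do.

Outcomes follow a per-hectare rate model,
$y = a \cdot (\gamma_0 + \gamma^\top z) + \tau\,\mathbb{1}\{\text{treated}\} + \varepsilon$:
the only linear family whose totals telescope exactly under merging (the
agglomerate's summed outcome equals the same model at its area-weighted
covariates).  The default sets $\gamma = 0$: outcomes are then exactly
linear in the unit-level covariates through area, the outcome regression
is correctly specified, and confounding is still severe — outcomes scale
with area and treated units are ~20× larger, so the naive contrast is
biased by roughly +100 ha against an injected ATT of 10 ha.  Non-zero
per-hectare slopes are exposed (`gain_model$slopes`) for stress tests;
they introduce area×covariate curvature that an additive linear outcome
model can only approximate, leaving design-stage conditional bias that no
sandwich standard error can cover — worth knowing before interpreting
real-data results, where rate heterogeneity is certain.

`generate_landscape()` plants connected components with scripted
trajectories — gains, reversals, mature losses, too-recent regrowth,
sub-threshold blobs of exactly 10 and 11 pixels around the mapping-unit
boundary, and isolated single-pixel flickers — one per placement cell with
margins, so components never touch and the exact expected per-territory
outcome table is known by construction and returned alongside the stack.

What passing on this testbed does *not* show: real mask stacks carry
classification noise and spatial autocorrelation, real covariates are not
Gaussian, real outcome surfaces are not single-rate linear, and real
candidate pools are ~1,000× larger relative to K.  The synthetic results
validate the machinery and its statistical calibration under the stated
model, not biome-scale conclusions.

## Problem sizes and numerical choices

The reference study conditions used throughout the tests and the
acceptance script are 30 treated / 2,000 controls, K = 500 candidates and
20 repeated runs; the estimator checks use 100 recovery seeds and 500 null
replicates; trajectory checks use 72×72×38 scripted landscapes and 20×20×38
random stacks against a brute-force oracle.  Greedy acceptance requires a
*strict* distance decrease; ANN queries examine `max(2K, 64)` candidates
before exact re-ranking; min-cost-flow tolerances are $10^{-12}$ on reduced
costs; zero-variance covariates standardize to 0 with a warning rather
than erroring; degenerate full-matching strata cannot arise by
construction (every unit is covered by a star).  Per-run seeds derive
deterministically from the master seed and stay within R's 32-bit integer
range.
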