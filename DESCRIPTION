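Package: agglomatch
Title: Agglomerative Matching for Causal Inference on Land-Tenure Territories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the effect of land-tenure regimes on
    long-term forest restoration outcomes when treatment territories are
    few and large while candidate controls are numerous and small.
    Implements agglomerative matching: for each treatment territory a
    synthetic "agglomerate" control is grown by greedily merging candidate
    control territories drawn from an approximate nearest-neighbour index,
    summing summable covariates (area, outcome totals) and area-weighting
    the rest, until the agglomerate reaches the target's size or no merge
    improves the standardized L2 covariate distance.  Includes balance
    diagnostics (standardized mean differences, prognostic scores,
    mini-max run selection over repeated stochastic matches), optimal full
    matching by minimum-cost network flow, doubly-robust average treatment
    effect on the treated (ATT) estimation with cluster-robust standard
    errors, a trajectory classifier that turns annual forest/non-forest
    masks into per-territory hectares of long-term restoration gains and
    restoration reversals, and a synthetic-data module with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    tiff
Config/testthat/edition: 3
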