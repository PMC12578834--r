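## Synthetic data with known ground truth, for end-to-end validation of the
## matching, estimation and trajectory modules without any external data.

.cov_names <- c("forest1985_pct", "temperature", "precipitation", "slope",
                "elevation", "dist_roads", "dist_rivers", "dist_city",
                "pop_density")

.default_cov_means <- c(forest1985_pct = 40, temperature = 21,
                        precipitation = 1400, slope = 12, elevation = 500,
                        dist_roads = 5, dist_rivers = 2, dist_city = 30,
                        pop_density = 25)
.default_cov_sds <- c(forest1985_pct = 15, temperature = 2,
                      precipitation = 250, slope = 6, elevation = 250,
                      dist_roads = 3, dist_rivers = 1.5, dist_city = 15,
                      pop_density = 20)
# treated territories sit on remoter, steeper, wetter land (shifts in
# control-SD units), calibrated so the pre-matching max |SMD| sits clearly
# above the 0.1 balance threshold (~0.2-0.3) and covariates confound the
# outcomes unless matched away
.default_treat_shift <- c(forest1985_pct = 0.2, temperature = -0.12,
                          precipitation = 0.12, slope = 0.2, elevation = 0.16,
                          dist_roads = 0.25, dist_rivers = 0.08,
                          dist_city = 0.2, pop_density = -0.2)

.default_correlation <- local({
  R <- diag(9)
  dimnames(R) <- list(.cov_names, .cov_names)
  set_cor <- function(R, a, b, r) { R[a, b] <- R[b, a] <- r; R }
  R <- set_cor(R, "slope", "elevation", 0.5)
  R <- set_cor(R, "temperature", "elevation", -0.6)
  R <- set_cor(R, "precipitation", "elevation", 0.3)
  R <- set_cor(R, "dist_roads", "dist_city", 0.5)
  R <- set_cor(R, "pop_density", "dist_city", -0.4)
  R <- set_cor(R, "forest1985_pct", "slope", 0.3)
  R
})

# per-hectare outcome rates are linear in standardized covariates, so the
# summed outcome of an agglomerate equals the same rate model evaluated at
# its area-weighted covariates.  The default rate is homogeneous (zero
# per-hectare covariate slopes): outcomes are then exactly linear in the
# unit-level covariates (through area), the regression estimator is
# correctly specified, and outcome totals telescope under merging.
# Non-zero slopes are supported for stress tests; they introduce
# area x covariate curvature that an additive linear outcome model can
# only approximate.
.zero_slopes <- stats::setNames(rep(0, 9), .cov_names)
.default_gain_slopes <- .zero_slopes
.default_reversal_slopes <- .zero_slopes

#' Configuration for synthetic territory tables
#'
#' Defaults emulate the structural asymmetry that motivates agglomerative
#' matching: a few large treatment territories (median 2000 ha) against a
#' large pool of small private controls (median 100 ha, ratio roughly
#' 1:20, forcing multi-member agglomerates), covariate means shifted for
#' the treated group so that several covariates are imbalanced (|SMD| >
#' 0.1) and confound the outcomes, and a linear-Gaussian outcome model
#' with a known injected ATT.
#'
#' Outcomes are generated as `area_ha * (intercept + slopes . z) +
#' true_att * treated + noise`, with `z` the covariates standardized by the
#' configured control moments — a per-hectare rate model, so outcome totals
#' are summable exactly as territory areas are.
#'
#' @param n_treatment,n_control group sizes.
#' @param treatment_size,control_size lognormal area parameters
#'   (`meanlog`, `sdlog`), in hectares.
#' @param covariate_means,covariate_sds named vectors over the nine
#'   non-summable covariates (control population).
#' @param treat_shift_sd named vector of treated-group mean shifts, in
#'   control-SD units.
#' @param correlation 9x9 covariate correlation matrix.
#' @param gain_model,reversal_model lists with `intercept` and `slopes`
#'   (per-hectare rates against standardized covariates).
#' @param true_att_gain,true_att_reversal injected treatment effects, in
#'   hectares.
#' @param noise_sd outcome noise SD, in hectares.
#' @param seed RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_treatment = 30L, n_control = 2000L,
                             treatment_size = list(meanlog = log(2000), sdlog = 0.5),
                             control_size = list(meanlog = log(100), sdlog = 0.35),
                             covariate_means = .default_cov_means,
                             covariate_sds = .default_cov_sds,
                             treat_shift_sd = .default_treat_shift,
                             correlation = .default_correlation,
                             gain_model = list(intercept = 0.06,
                                               slopes = .default_gain_slopes),
                             reversal_model = list(intercept = 0.03,
                                                   slopes = .default_reversal_slopes),
                             true_att_gain = 10, true_att_reversal = -5,
                             noise_sd = 5, seed = 1L) {
  stopifnot(n_treatment >= 1, n_control >= n_treatment, noise_sd >= 0)
  for (s in list(treatment_size, control_size))
    if (!is.finite(s$meanlog) || !is.finite(s$sdlog) || s$sdlog < 0)
      stop("invalid lognormal size distribution parameters")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic territory table with known ground truth
#'
#' @param config a [synthetic_config()].
#' @return list with `territories` (a territory table ready for
#'   [run_matching()]: treated units first, integer ids) and `truth`
#'   (injected ATTs and the outcome-model coefficients).
#' @export
generate_territories <- function(config = synthetic_config()) {
  .with_seed(config$seed, {
    nt <- config$n_treatment; nc <- config$n_control; n <- nt + nc
    treat <- rep(c(1, 0), c(nt, nc))
    area <- c(stats::rlnorm(nt, config$treatment_size$meanlog,
                            config$treatment_size$sdlog),
              stats::rlnorm(nc, config$control_size$meanlog,
                            config$control_size$sdlog))
    L <- chol(config$correlation[.cov_names, .cov_names])
    Z <- matrix(stats::rnorm(n * 9), n, 9) %*% L
    colnames(Z) <- .cov_names
    X <- sapply(.cov_names, function(v)
      config$covariate_means[v] +
        config$treat_shift_sd[v] * config$covariate_sds[v] * treat +
        config$covariate_sds[v] * Z[, v])
    X[, "forest1985_pct"] <- pmin(pmax(X[, "forest1985_pct"], 0), 100)
    for (v in c("slope", "dist_roads", "dist_rivers", "dist_city", "pop_density"))
      X[, v] <- pmax(X[, v], 0)
    zs <- sweep(sweep(X, 2, config$covariate_means[.cov_names]), 2,
                config$covariate_sds[.cov_names], "/")
    rate_g <- config$gain_model$intercept +
      as.numeric(zs %*% config$gain_model$slopes[.cov_names])
    rate_r <- config$reversal_model$intercept +
      as.numeric(zs %*% config$reversal_model$slopes[.cov_names])
    gain <- area * rate_g + config$true_att_gain * treat +
      stats::rnorm(n, 0, config$noise_sd)
    reversal <- area * rate_r + config$true_att_reversal * treat +
      stats::rnorm(n, 0, config$noise_sd)
    territories <- data.frame(
      territory_id = seq_len(n),
      regime = ifelse(treat == 1, "indigenous_land", "private_property"),
      role = ifelse(treat == 1, "treatment", "control"),
      area_ha = area, X, gain_ha = gain, reversal_ha = reversal)
    list(territories = territories,
         truth = list(att_gain = config$true_att_gain,
                      att_reversal = config$true_att_reversal,
                      gain_model = config$gain_model,
                      reversal_model = config$reversal_model,
                      noise_sd = config$noise_sd))
  })
}

#' Configuration for synthetic annual-mask landscapes
#'
#' The landscape is a grid of territory bands seeded with connected
#' "planted" components, each following a scripted trajectory that realizes
#' one outcome category: long-term gains (regrowth persisting to the final
#' year for at least the gain threshold), reversals (3-10 years of regrowth
#' then cleared), mature losses (>10 years then cleared, excluded), and
#' too-recent regrowth, plus sub-threshold blobs and isolated single-pixel
#' "flickers" that must be removed by the minimum-mapping-unit filter.
#' Because every component's category and size are scripted, the exact
#' per-territory outcome table is known in advance and returned.
#'
#' @param nrow,ncol grid dimensions; `ncol` must split evenly into
#'   `n_territories` bands of whole placement cells.
#' @param years calendar years of the annual layers (span must be at least
#'   14 years so both gains and reversals are realizable).
#' @param n_territories number of vertical territory bands.
#' @param cell placement cell size in pixels; one component per cell, with a
#'   1-pixel margin, guarantees components never touch.
#' @param components list of `list(category, n_pixels)` planted per
#'   territory; categories: `"gain"`, `"reversal"`, `"mature_loss"`,
#'   `"too_recent"`, `"baseline"`.
#' @param flicker_prob probability that an unused placement cell holds one
#'   isolated flickering pixel (regrowth/clearing noise below any sensible
#'   mapping unit).
#' @param min_pixels minimum-mapping-unit used when computing the expected
#'   outcome table.
#' @param pixel_area_ha pixel area in hectares.
#' @param seed RNG seed.
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 72L, ncol = 72L, years = 1985:2022,
                             n_territories = 3L, cell = 12L,
                             components = list(
                               list(category = "gain", n_pixels = 20L),
                               list(category = "gain", n_pixels = 11L),
                               list(category = "gain", n_pixels = 10L),
                               list(category = "gain", n_pixels = 8L),
                               list(category = "reversal", n_pixels = 15L),
                               list(category = "mature_loss", n_pixels = 15L),
                               list(category = "too_recent", n_pixels = 12L),
                               list(category = "baseline", n_pixels = 36L)),
                             flicker_prob = 0.5, min_pixels = 11L,
                             pixel_area_ha = 0.09, seed = 1L) {
  if (length(years) < 14L)
    stop("the year span must cover at least 14 years")
  if (nrow %% cell != 0 || ncol %% n_territories != 0 ||
      (ncol %/% n_territories) %% cell != 0)
    stop("grid does not split into whole placement cells per territory band")
  structure(as.list(environment()), class = "landscape_config")
}

# random connected blob of n pixels grown by 4-neighbour accretion
.grow_blob <- function(n, rmin, rmax, cmin, cmax) {
  pts <- matrix(c(sample(rmin:rmax, 1L), sample(cmin:cmax, 1L)), 1, 2)
  while (nrow(pts) < n) {
    base <- pts[sample.int(nrow(pts), 1L), ]
    step <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[sample.int(4L, 1L), ]
    cand <- base + step
    if (cand[1] < rmin || cand[1] > rmax || cand[2] < cmin || cand[2] > cmax)
      next
    if (!any(pts[, 1] == cand[1] & pts[, 2] == cand[2]))
      pts <- rbind(pts, cand)
  }
  pts
}

#' Generate a synthetic annual-mask landscape with known outcomes
#'
#' @param config a [landscape_config()].
#' @return list with `stack` (logical rows x cols x years array),
#'   `territory_ids` (integer matrix of territory bands), `expected`
#'   (exact per-territory outcome table for the configured mapping unit),
#'   and `components` (the placed component ledger).
#' @export
generate_landscape <- function(config = landscape_config()) {
  .with_seed(config$seed, {
    nr <- config$nrow; ncg <- config$ncol
    years <- config$years; ny <- length(years)
    y0 <- min(years); y1 <- max(years)
    cell <- config$cell
    band_w <- ncg %/% config$n_territories
    cells_r <- nr %/% cell; cells_c <- band_w %/% cell
    n_cells <- cells_r * cells_c
    if (length(config$components) > n_cells)
      stop("components do not fit one-per-cell without overlap")
    stack <- array(FALSE, dim = c(nr, ncg, ny))
    territory_ids <- matrix(rep(seq_len(config$n_territories),
                                each = band_w), nr, ncg, byrow = TRUE)
    ledger <- list()
    for (terr in seq_len(config$n_territories)) {
      col0 <- (terr - 1L) * band_w
      cells <- sample.int(n_cells)       # cell order for this territory
      used <- length(config$components)
      for (ci in seq_along(config$components)) {
        comp <- config$components[[ci]]
        cidx <- cells[ci] - 1L
        rmin <- (cidx %% cells_r) * cell + 2L
        cmin <- col0 + (cidx %/% cells_r) * cell + 2L
        pts <- .grow_blob(comp$n_pixels, rmin, rmin + cell - 3L,
                          cmin, cmin + cell - 3L)
        traj <- .component_years(comp$category, y0, y1)
        for (yy in traj$forest_years) {
          k <- match(yy, years)
          stack[cbind(pts[, 1], pts[, 2], k)] <- TRUE
        }
        ledger[[length(ledger) + 1L]] <- data.frame(
          territory_id = terr, category = comp$category,
          n_pixels = comp$n_pixels, start_year = traj$start,
          duration = traj$duration)
      }
      for (ci in if (used < n_cells) seq.int(used + 1L, n_cells) else integer(0)) {
        if (stats::runif(1) > config$flicker_prob) next  # flicker in free cell
        cidx <- cells[ci] - 1L
        rmin <- (cidx %% cells_r) * cell + 2L
        cmin <- col0 + (cidx %/% cells_r) * cell + 2L
        pt <- c(sample(rmin:(rmin + cell - 3L), 1L),
                sample(cmin:(cmin + cell - 3L), 1L))
        traj <- .component_years(sample(c("gain", "reversal"), 1L), y0, y1)
        for (yy in traj$forest_years)
          stack[pt[1], pt[2], match(yy, years)] <- TRUE
        ledger[[length(ledger) + 1L]] <- data.frame(
          territory_id = terr, category = "flicker", n_pixels = 1L,
          start_year = traj$start, duration = traj$duration)
      }
    }
    components <- do.call(rbind, ledger)
    npix_terr <- nr * band_w
    counted <- function(cat) {
      ok <- components$category == cat & components$n_pixels >= config$min_pixels
      tapply(components$n_pixels * ok, components$territory_id, sum)
    }
    base_px <- tapply(components$n_pixels * (components$category == "baseline"),
                      components$territory_id, sum)
    expected <- data.frame(
      territory_id = seq_len(config$n_territories),
      gain_ha = as.numeric(counted("gain")) * config$pixel_area_ha,
      reversal_ha = as.numeric(counted("reversal")) * config$pixel_area_ha,
      forest_1985_pct = 100 * as.numeric(base_px) / npix_terr)
    list(stack = stack, territory_ids = territory_ids, expected = expected,
         components = components, config = config)
  })
}

# scripted forest years realizing one outcome category
.component_years <- function(category, y0, y1) {
  gmin <- 10L; dmin <- 3L; prior <- 3L
  switch(category,
    baseline = list(forest_years = y0:y1, start = y0, duration = y1 - y0 + 1L),
    gain = {
      s <- sample((y0 + prior):(y1 - gmin + 1L), 1L)
      list(forest_years = s:y1, start = s, duration = y1 - s + 1L)
    },
    too_recent = {
      s <- sample((y1 - gmin + 2L):(y1 - dmin + 1L), 1L)
      list(forest_years = s:y1, start = s, duration = y1 - s + 1L)
    },
    reversal = {
      d <- sample(dmin:10L, 1L)
      s <- sample((y0 + prior):(y1 - d), 1L)
      list(forest_years = s:(s + d - 1L), start = s, duration = d)
    },
    mature_loss = {
      d <- sample(11L:min(20L, y1 - (y0 + prior)), 1L)
      s <- sample((y0 + prior):(y1 - d), 1L)
      list(forest_years = s:(s + d - 1L), start = s, duration = d)
    },
    stop("unknown component category: ", category))
}
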