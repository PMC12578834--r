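# Independent brute-force oracles, written without reusing the package's
# internal machinery, for cross-checking the implementation on small inputs.

# --- trajectory oracle: index-arithmetic reimplementation (no rle) ---------

oracle_pixel_categories <- function(series, first_year) {
  ny <- length(series)
  fy <- which(as.logical(series))
  out <- list()
  if (!length(fy)) return(out)
  runs <- split(fy, cumsum(c(1, diff(fy) != 1)))
  for (run in runs) {
    s <- run[1]; e <- run[length(run)]
    dur <- e - s + 1
    prior <- if (s == 1) 0 else {
      # consecutive non-forest years immediately before s
      k <- 0; j <- s - 1
      while (j >= 1 && !series[j]) { k <- k + 1; j <- j - 1 }
      k
    }
    persists <- e == ny
    cat_ <- if (prior < 3 || dur < 3) "not_restoration"
      else if (persists && dur >= 10) "long_term_gain"
      else if (persists) "too_recent"
      else if (dur <= 10) "reversal"
      else "excluded_mature_loss"
    out[[length(out) + 1]] <- list(category = cat_,
                                   start_year = first_year + s - 1)
  }
  out
}

# label propagation connected components (not flood fill)
oracle_components <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (r in 1:nr) for (cc in 1:nc) {
      if (!mask[r, cc]) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        if (connectivity == 4 && abs(dr) + abs(dc) != 1) next
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
        if (mask[rr, c2] && lab[rr, c2] < lab[r, cc]) {
          lab[r, cc] <- lab[rr, c2]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# full pipeline oracle: stack -> per-territory gain/reversal hectares
oracle_territory_outcomes <- function(stack, territory_ids, first_year = 1985,
                                      min_pixels = 11, connectivity = 8,
                                      pixel_area_ha = 0.09) {
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  cat_start <- list(long_term_gain = matrix(0L, nr, nc),
                    reversal = matrix(0L, nr, nc))
  for (r in 1:nr) for (cc in 1:nc) {
    for (ep in oracle_pixel_categories(stack[r, cc, ], first_year)) {
      if (ep$category %in% names(cat_start) &&
          cat_start[[ep$category]][r, cc] == 0L)
        cat_start[[ep$category]][r, cc] <- ep$start_year
    }
  }
  for (cat_ in names(cat_start)) {
    m <- cat_start[[cat_]]
    for (y in setdiff(unique(as.vector(m)), 0L)) {
      comp <- oracle_components(m == y, connectivity)
      for (k in setdiff(unique(as.vector(comp)), 0L))
        if (sum(comp == k) < min_pixels) m[comp == k & m == y] <- 0L
    }
    cat_start[[cat_]] <- m
  }
  ids <- sort(setdiff(unique(as.vector(territory_ids)), 0L))
  do.call(rbind, lapply(ids, function(i) {
    inT <- territory_ids == i
    data.frame(territory_id = i,
               gain_ha = sum(cat_start$long_term_gain > 0 & inT) * pixel_area_ha,
               reversal_ha = sum(cat_start$reversal > 0 & inT) * pixel_area_ha,
               forest_1985_pct = 100 * sum(stack[, , 1] & inT) / sum(inT))
  }))
}

# --- agglomeration oracle: exhaustive best subset --------------------------

# merged covariates of a member subset are order-independent: summables sum,
# non-summables are area-weighted means
oracle_best_subset_distance <- function(target, candidates, scaler, schema) {
  m <- nrow(candidates)
  dv <- schema$distance_vars
  best <- Inf
  a <- candidates$area_ha
  X <- as.matrix(candidates[, schema$non_summable, drop = FALSE])
  tgt <- as.numeric(target[dv])
  sdv <- scaler$sd[dv]
  for (code in 1:(2^m - 1)) {
    sel <- as.logical(bitwAnd(code, 2^(0:(m - 1))))
    A <- sum(a[sel])
    xm <- colSums(a[sel] * X[sel, , drop = FALSE]) / A
    d <- sqrt(sum(((c(A, xm) - tgt) / sdv)^2))
    if (d < best) best <- d
  }
  best
}

# --- full matching oracle: enumerate all star forests ----------------------

# every full match is a disjoint set of stars; enumerate assignments of each
# control to a treated center (or center status), then attach free treated
# units to control centers
oracle_full_match_distance <- function(d) {
  nt <- nrow(d); nc <- ncol(d)
  ctrl_opts <- rev(expand.grid(rep(list(0:nt), nc)))  # 0 = control is center
  best <- Inf
  for (i in seq_len(nrow(ctrl_opts))) {
    assign_c <- as.integer(ctrl_opts[i, ])
    centers_c <- which(assign_c == 0)
    attached_t <- unique(assign_c[assign_c > 0])
    free_t <- setdiff(seq_len(nt), attached_t)
    cost0 <- sum(d[cbind(assign_c[assign_c > 0], which(assign_c > 0))])
    if (!length(free_t)) {
      if (!length(centers_c)) best <- min(best, cost0)
      next
    }
    if (!length(centers_c)) next
    ft_opts <- rev(expand.grid(rep(list(centers_c), length(free_t))))
    for (j in seq_len(nrow(ft_opts))) {
      assign_t <- as.integer(ft_opts[j, ])
      if (!all(centers_c %in% assign_t)) next  # every center needs >= 1
      best <- min(best, cost0 + sum(d[cbind(free_t, assign_t)]))
    }
  }
  best
}

# --- small fixtures --------------------------------------------------------

tiny_schema <- function() {
  covariate_schema(summable = "area_ha", non_summable = c("temperature", "slope"),
                   outcomes = "gain_ha")
}

tiny_records <- function(n, seed = 1, role = "control", id0 = 100L) {
  set.seed(seed)
  data.frame(territory_id = id0 + seq_len(n), regime = "private_property",
             role = role,
             area_ha = stats::rlnorm(n, log(50), 0.4),
             temperature = stats::rnorm(n, 20, 2),
             slope = stats::rnorm(n, 10, 3),
             gain_ha = stats::rnorm(n, 5, 1))
}
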