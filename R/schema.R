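#' Covariate schema for territory records
#'
#' Declares which territory columns are *summable* (added when territories are
#' merged into an agglomerate: area and outcome totals) and which are
#' *non-summable* (merged by area-weighted average: climatic, topographic and
#' accessibility covariates expressed as per-territory means).
#'
#' The default schema carries the ten matching covariates used throughout the
#' package: territory size (`area_ha`), percent forest cover in the first
#' observed year (`forest1985_pct`), mean temperature, precipitation, slope,
#' elevation, distance to roads, rivers and the nearest city, and population
#' density.
#'
#' @param summable character vector of summable covariate names. Must include
#'   `"area_ha"`, which drives the area-weighted average.
#' @param non_summable character vector of non-summable covariate names.
#' @param outcomes character vector of outcome columns (summable by nature,
#'   but never used in matching distances).
#' @return An object of class `covariate_schema` with elements `summable`,
#'   `non_summable`, `outcomes`, `distance_vars` (all ten covariates, used in
#'   the greedy L2 objective) and `ann_vars` (the non-summables, used by the
#'   approximate nearest-neighbour index).
#' @export
#' @examples
#' sch <- covariate_schema()
#' sch$distance_vars
covariate_schema <- function(summable = "area_ha",
                             non_summable = c("forest1985_pct", "temperature",
                                              "precipitation", "slope", "elevation",
                                              "dist_roads", "dist_rivers",
                                              "dist_city", "pop_density"),
                             outcomes = c("gain_ha", "reversal_ha")) {
  if (!"area_ha" %in% summable)
    stop("schema must declare 'area_ha' as a summable covariate")
  if (length(intersect(summable, non_summable)))
    stop("summable and non_summable covariates must be disjoint")
  structure(list(summable = summable,
                 non_summable = non_summable,
                 outcomes = outcomes,
                 distance_vars = c(summable, non_summable),
                 ann_vars = non_summable),
            class = "covariate_schema")
}

#' Standardize covariates against a frozen reference population
#'
#' Computes per-covariate mean and standard deviation on a reference sample
#' (by default the pooled, unmatched treatment + control records) and returns
#' both the standardized matrix and the scaler, so that agglomerates built
#' later can be standardized identically.  Zero-variance covariates are
#' retained with all standardized values 0 (scale set to 1) and a warning.
#'
#' @param records data.frame of territory records.
#' @param schema a [covariate_schema()].
#' @param vars which covariates to standardize (default: all distance
#'   covariates).
#' @param scaler optional scaler (as returned in `$scaler`) to reuse instead
#'   of recomputing; used to project new units onto a frozen scale.
#' @return list with `z` (matrix of standardized values, one row per record)
#'   and `scaler` (list with `mean` and `sd`, named by covariate).
#' @export
standardize_covariates <- function(records, schema = covariate_schema(),
                                   vars = schema$distance_vars, scaler = NULL) {
  x <- as.matrix(records[, vars, drop = FALSE])
  if (anyNA(x)) stop("missing covariate values; filter records first")
  if (is.null(scaler)) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    if (any(!is.finite(sdv) | sdv == 0)) {
      bad <- vars[!is.finite(sdv) | sdv == 0]
      warning("zero-variance covariate(s) standardized to 0: ",
              paste(bad, collapse = ", "))
      sdv[!is.finite(sdv) | sdv == 0] <- 1
    }
    scaler <- list(mean = mu, sd = sdv)
  }
  z <- sweep(sweep(x, 2, scaler$mean[vars]), 2, scaler$sd[vars], "/")
  list(z = z, scaler = scaler)
}

# standardize a single named vector with a frozen scaler
.standardize_vec <- function(v, scaler, vars) {
  (as.numeric(v[vars]) - scaler$mean[vars]) / scaler$sd[vars]
}

#' Merge a territory into an agglomerate record
#'
#' Summable covariates (area, outcome totals) are added; non-summable
#' covariates are combined by area-weighted average, so the merged value of a
#' per-hectare mean is the mean over the union of the members' area.
#' An empty (`NULL`) agglomerate merged with `unit` yields `unit`.
#'
#' @param current named list / one-row data.frame for the current agglomerate,
#'   or `NULL` for the empty agglomerate.
#' @param unit named list / one-row data.frame for the territory to merge.
#' @param schema a [covariate_schema()].
#' @return named list with merged summables, non-summables and outcomes.
#' @export
#' @examples
#' sch <- covariate_schema(summable = "area_ha", non_summable = "temperature",
#'                         outcomes = "gain_ha")
#' a <- list(area_ha = 30, temperature = 18, gain_ha = 2)
#' b <- list(area_ha = 10, temperature = 22, gain_ha = 1)
#' merge_units(a, b, sch)$temperature  # (30*18 + 10*22)/40 = 19
merge_units <- function(current, unit, schema = covariate_schema()) {
  fields <- c(schema$summable, schema$non_summable, schema$outcomes)
  unit <- as.list(unit)[fields]
  if (is.null(current)) return(unit)
  current <- as.list(current)[fields]
  a_c <- current$area_ha
  a_u <- unit$area_ha
  if (a_c + a_u <= 0) stop("merged area must be positive")
  out <- current
  for (f in c(schema$summable, schema$outcomes))
    out[[f]] <- current[[f]] + unit[[f]]
  w <- a_c / (a_c + a_u)
  for (f in schema$non_summable)
    out[[f]] <- w * current[[f]] + (1 - w) * unit[[f]]
  out
}
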