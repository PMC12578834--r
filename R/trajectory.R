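#' Rules for classifying forest regrowth episodes
#'
#' A regrowth episode (a maximal run of consecutive forest years in a
#' pixel's annual forest/non-forest series) is a *restoration* episode only
#' if the pixel was non-forested for at least `min_prior_nonforest`
#' consecutive years immediately before regrowth and the forest persisted at
#' least `min_duration` years.  Restoration episodes are then split into:
#' \describe{
#'   \item{long_term_gain}{persisted at least `gain_min_duration` years and
#'     through the final observed year;}
#'   \item{reversal}{persisted between `min_duration` and
#'     `reversal_max_duration` years (inclusive) and was deforested before
#'     the final year;}
#'   \item{excluded_mature_loss}{persisted longer than
#'     `reversal_max_duration` years but was later deforested (excluded from
#'     both outcome classes);}
#'   \item{too_recent}{still forested in the final year but younger than
#'     `gain_min_duration` years (not yet classifiable).}
#' }
#' Forest already present in the first observed year has no observable prior
#' non-forest window and is treated as baseline forest (`not_restoration`).
#'
#' @param min_prior_nonforest minimum consecutive non-forest years before
#'   regrowth (years).
#' @param min_duration minimum persistence for any restoration episode
#'   (years).
#' @param gain_min_duration minimum persistence of a long-term gain (years).
#' @param reversal_max_duration maximum persistence of a reversal (years,
#'   inclusive).
#' @return list of class `trajectory_rules`.
#' @export
trajectory_rules <- function(min_prior_nonforest = 3L, min_duration = 3L,
                             gain_min_duration = 10L,
                             reversal_max_duration = 10L) {
  structure(list(min_prior_nonforest = min_prior_nonforest,
                 min_duration = min_duration,
                 gain_min_duration = gain_min_duration,
                 reversal_max_duration = reversal_max_duration),
            class = "trajectory_rules")
}

#' Detect regrowth episodes in one pixel's annual series
#'
#' Run-length encodes the boolean forest series and returns every maximal
#' run of consecutive forest years, annotated with the number of
#' consecutive non-forest years immediately preceding it (0 for a run that
#' starts in the first observed year) and whether it persists to the end of
#' the series.
#'
#' @param values logical (or 0/1) vector, one entry per year, `TRUE` =
#'   forest.
#' @param first_year calendar year of the first entry.
#' @return data.frame with one row per episode: `start_year`, `end_year`,
#'   `duration_years`, `prior_nonforest_years`, `persists_to_series_end`.
#' @export
#' @examples
#' detect_episodes(c(rep(FALSE, 16), rep(TRUE, 22)), first_year = 1985)
detect_episodes <- function(values, first_year = 1985L) {
  if (!length(values)) stop("empty pixel series")
  values <- as.logical(values)
  if (anyNA(values)) stop("pixel series contains missing values")
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  prior <- ifelse(keep == 1L, 0L, r$lengths[pmax(keep - 1L, 1L)])
  data.frame(start_year = first_year + starts[keep] - 1L,
             end_year = first_year + ends[keep] - 1L,
             duration_years = r$lengths[keep],
             prior_nonforest_years = as.integer(prior),
             persists_to_series_end = ends[keep] == length(values))
}

#' Classify a regrowth episode
#'
#' Applies [trajectory_rules()] to one episode (or, vectorized, to every row
#' of a [detect_episodes()] result).
#'
#' @param episode one-row data.frame (or a multi-row episode table).
#' @param rules a [trajectory_rules()].
#' @return character vector of categories: `"long_term_gain"`,
#'   `"reversal"`, `"excluded_mature_loss"`, `"too_recent"` or
#'   `"not_restoration"`.
#' @export
classify_episode <- function(episode, rules = trajectory_rules()) {
  dur <- episode$duration_years
  prior <- episode$prior_nonforest_years
  persists <- episode$persists_to_series_end
  out <- rep("not_restoration", length(dur))
  ok <- prior >= rules$min_prior_nonforest & dur >= rules$min_duration
  out[ok & persists & dur >= rules$gain_min_duration] <- "long_term_gain"
  out[ok & persists & dur < rules$gain_min_duration] <- "too_recent"
  out[ok & !persists & dur <= rules$reversal_max_duration] <- "reversal"
  out[ok & !persists & dur > rules$reversal_max_duration] <- "excluded_mature_loss"
  out
}

#' Classify every pixel of an annual forest-mask stack
#'
#' Runs [detect_episodes()] and [classify_episode()] on every pixel of a
#' rows x cols x years boolean array.  Each regrowth episode of a pixel is
#' classified independently, so a pixel can contribute a reversal from an
#' early episode and a long-term gain from a later one; per category the
#' episode start year is recorded (the earliest qualifying episode, should a
#' pixel ever have two of the same category) for start-year-cohort
#' connectivity filtering.
#'
#' @param stack logical/0-1 array `[rows, cols, years]`.
#' @param first_year calendar year of the first layer.
#' @param rules a [trajectory_rules()].
#' @return object of class `trajectory_labels`: list with `start_year` (one
#'   integer matrix per outcome category, 0 = category absent), `counts`
#'   (episodes per category), `baseline_forest` (first-year mask),
#'   `first_year`, `last_year`, `dim`.
#' @export
classify_stack <- function(stack, first_year = 1985L,
                           rules = trajectory_rules()) {
  stopifnot(length(dim(stack)) == 3L)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; ny <- dim(stack)[3]
  cats <- c("long_term_gain", "reversal", "excluded_mature_loss",
            "too_recent", "not_restoration")
  sy <- list(long_term_gain = matrix(0L, nr, nc),
             reversal = matrix(0L, nr, nc))
  counts <- stats::setNames(numeric(length(cats)), cats)
  flat <- matrix(stack, nr * nc, ny)      # one row per pixel
  active <- which(rowSums(flat) > 0)
  for (p in active) {
    ep <- detect_episodes(flat[p, ], first_year)
    lab <- classify_episode(ep, rules)
    for (cat in names(sy)) {
      hit <- which(lab == cat)
      if (length(hit)) sy[[cat]][p] <- ep$start_year[hit[1L]]
    }
    tb <- table(lab)
    counts[names(tb)] <- counts[names(tb)] + tb
  }
  structure(list(start_year = sy, counts = counts,
                 baseline_forest = matrix(as.logical(stack[, , 1]), nr, nc),
                 first_year = as.integer(first_year),
                 last_year = as.integer(first_year + ny - 1L),
                 dim = c(nr, nc)),
            class = "trajectory_labels")
}

#' Label connected components of a binary mask
#'
#' Flood-fill labelling under 4- (rook) or 8- (queen) connectivity.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  if (connectivity == 4) { dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L) }
  else {
    dr <- rep(-1:1, times = 3); dc <- rep(-1:1, each = 3)
    keep <- !(dr == 0 & dc == 0); dr <- dr[keep]; dc <- dc[keep]
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (p in which(mask)) {
    if (lab[p]) next
    cur <- cur + 1L
    queue <- p; lab[p] <- cur
    while (length(queue)) {
      q0 <- queue[[1L]]; queue <- queue[-1L]
      r <- (q0 - 1L) %% nr + 1L; cc <- (q0 - 1L) %/% nr + 1L
      rr <- r + dr; c2 <- cc + dc
      ok <- rr >= 1L & rr <= nr & c2 >= 1L & c2 <= nc
      pp <- (c2[ok] - 1L) * nr + rr[ok]
      new <- pp[mask[pp] & lab[pp] == 0L]
      if (length(new)) { lab[new] <- cur; queue <- c(queue, new) }
    }
  }
  lab
}

#' Minimum-mapping-unit filter on labelled trajectories
#'
#' Removes connected components of an outcome category with fewer than
#' `min_pixels` pixels (they are relabelled `not_restoration`, i.e. dropped
#' from the category).  Components are computed among pixels that share both
#' the category and the episode start year, so unrelated events that happen
#' to touch are not merged into one component.
#'
#' @param labels a `trajectory_labels` object from [classify_stack()].
#' @param category one or more of `"long_term_gain"`, `"reversal"`.
#' @param min_pixels components smaller than this are removed (default 11:
#'   components with fewer than 11 connected pixels are excluded).
#' @param connectivity 4 or 8.
#' @param group_by_start_year logical; `FALSE` computes components over all
#'   pixels of the category jointly.
#' @return the filtered `trajectory_labels` object.
#' @export
filter_connected <- function(labels, category = c("long_term_gain", "reversal"),
                             min_pixels = 11L, connectivity = 8,
                             group_by_start_year = TRUE) {
  stopifnot(min_pixels >= 1L)
  for (cat in category) {
    m <- labels$start_year[[cat]]
    if (is.null(m)) stop("unknown category: ", cat)
    groups <- if (group_by_start_year) setdiff(unique(as.integer(m)), 0L) else -1L
    for (g in groups) {
      mask <- if (group_by_start_year) m == g else m > 0L
      comp <- label_components(mask, connectivity)
      sizes <- tabulate(comp)
      small <- which(sizes < min_pixels)
      if (length(small)) m[comp %in% small] <- 0L
    }
    labels$start_year[[cat]] <- m
  }
  labels
}

#' Aggregate labelled pixels to per-territory hectares
#'
#' Counts, per territory, the pixels labelled long-term gain and reversal
#' and converts them to hectares; also reports the percentage of each
#' territory forested in the first observed year.  Pixels with territory id
#' 0 belong to no territory and are ignored.
#'
#' @param labels a (filtered) `trajectory_labels` object.
#' @param territory_ids integer matrix congruent with the label grids; 0 =
#'   no territory.
#' @param pixel_area_ha area of one pixel in hectares (default 0.09, a 30 m
#'   pixel).
#' @return data.frame with `territory_id`, `gain_ha`, `reversal_ha`,
#'   `forest_1985_pct`, one row per territory present in `territory_ids`.
#' @export
aggregate_territory <- function(labels, territory_ids, pixel_area_ha = 0.09) {
  stopifnot(pixel_area_ha > 0)
  if (!all(dim(territory_ids) == labels$dim))
    stop("territory raster shape does not match the label grids")
  ids <- sort(setdiff(unique(as.integer(territory_ids)), 0L))
  if (!length(ids))
    return(data.frame(territory_id = integer(0), gain_ha = numeric(0),
                      reversal_ha = numeric(0), forest_1985_pct = numeric(0)))
  tv <- as.integer(territory_ids)
  count_in <- function(mask) {
    tb <- tapply(as.numeric(mask), tv, sum)
    out <- tb[as.character(ids)]; out[is.na(out)] <- 0; as.numeric(out)
  }
  npix <- count_in(matrix(TRUE, labels$dim[1], labels$dim[2]))
  data.frame(territory_id = ids,
             gain_ha = count_in(labels$start_year$long_term_gain > 0L) *
               pixel_area_ha,
             reversal_ha = count_in(labels$start_year$reversal > 0L) *
               pixel_area_ha,
             forest_1985_pct = 100 * count_in(labels$baseline_forest) / npix)
}

#' Per-territory restoration outcomes from an annual mask stack
#'
#' Full trajectory pipeline: episode detection and classification
#' ([classify_stack()]), minimum-mapping-unit filtering
#' ([filter_connected()]) and territory aggregation
#' ([aggregate_territory()]).
#'
#' @inheritParams classify_stack
#' @inheritParams filter_connected
#' @inheritParams aggregate_territory
#' @return see [aggregate_territory()].
#' @export
territory_outcomes <- function(stack, territory_ids, first_year = 1985L,
                               rules = trajectory_rules(), min_pixels = 11L,
                               connectivity = 8, pixel_area_ha = 0.09) {
  labels <- classify_stack(stack, first_year, rules)
  labels <- filter_connected(labels, min_pixels = min_pixels,
                             connectivity = connectivity)
  aggregate_territory(labels, territory_ids, pixel_area_ha)
}
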