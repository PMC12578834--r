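#' Matching configuration
#'
#' Collects the tunable parameters of agglomerative matching.  Defaults
#' follow the reference analysis: candidate lists of size `K = 10000` from
#' the approximate nearest-neighbour index, and `n_runs = 500` repeated
#' stochastic constructions per treatment territory.  Desk-scale analyses
#' pass smaller values explicitly.
#'
#' @param K candidate-list size per treatment territory (capped at the size
#'   of the control pool).
#' @param n_runs number of repeated matching runs (each with its own derived
#'   seed) over which balance is later compared.
#' @param seed master RNG seed; run `r` uses a seed derived from it.
#' @param standardization reference population for the frozen covariate
#'   scaler: `"treated"` (default; the ATT convention, consistent with the
#'   SMD denominator, and robust to the treated group's much larger areas
#'   inflating a pooled scale) or `"pooled"`.
#' @param ofm logical: re-match treated units to agglomerates with optimal
#'   full matching before estimation.
#' @param common_support logical: drop control units whose standardized
#'   covariates fall outside the treated group's per-covariate range before
#'   optimal full matching.
#' @param cr_type cluster-robust variance flavour, `"CR0"`, `"CR1"` or
#'   `"CR2"` (see [cluster_robust_se()]).
#' @param ann_trees,ann_leaf_size,search_k forwarded to [ann_index()] /
#'   [ann_query()].
#' @return list of class `match_config`.
#' @export
match_config <- function(K = 10000L, n_runs = 500L, seed = 1L,
                         standardization = c("treated", "pooled"),
                         ofm = TRUE, common_support = FALSE,
                         cr_type = c("CR1", "CR0", "CR2"),
                         ann_trees = 10L, ann_leaf_size = 32L,
                         search_k = NULL) {
  stopifnot(K >= 1, n_runs >= 1)
  structure(list(K = as.integer(K), n_runs = as.integer(n_runs),
                 seed = as.integer(seed),
                 standardization = match.arg(standardization), ofm = ofm,
                 common_support = common_support,
                 cr_type = match.arg(cr_type),
                 ann_trees = as.integer(ann_trees),
                 ann_leaf_size = as.integer(ann_leaf_size),
                 search_k = search_k),
            class = "match_config")
}

# frozen covariate scaler under the configured reference population
.make_scaler <- function(treatments, controls, schema, config) {
  ref <- if (identical(config$standardization, "pooled"))
    rbind(treatments[, schema$distance_vars], controls[, schema$distance_vars])
  else treatments
  standardize_covariates(ref, schema)$scaler
}

# deterministic per-run seed derived from the master seed; kept within
# the 32-bit integer range R requires of set.seed()
derive_seed <- function(master_seed, run) {
  as.integer(((as.numeric(master_seed) %% 2147483647) * 48271 +
                as.numeric(run) * 104729) %% 2147483647)
}

#' Grow one agglomerated control for a treatment territory
#'
#' Greedy loop over a candidate list: at each step every remaining candidate
#' is provisionally merged into the current agglomerate `C` (summables
#' summed, non-summables area-weighted, see [merge_units()]) and the
#' candidate whose merge brings `C` closest to the target in the L2 norm of
#' the standardized covariates (all ten, including area) is accepted.  The
#' first merge is unconditional (it seeds the empty agglomerate with the
#' closest single candidate).  The loop stops when
#' \itemize{
#'   \item the accepted merge pushes the agglomerate's area past the
#'     target's area (the overshooting merge is kept) — `"area_exceeded"`;
#'   \item no candidate strictly decreases the distance —
#'     `"no_improvement"`; or
#'   \item the candidate list is exhausted — `"candidates_exhausted"`.
#' }
#' Exact distance ties are broken towards the lowest `territory_id` so runs
#' are reproducible.
#'
#' @param target one-row data.frame (or named list) for the treatment
#'   territory.
#' @param candidates data.frame of candidate control territories (the
#'   candidate list returned by the ANN query).
#' @param schema a [covariate_schema()].
#' @param scaler frozen scaler from [standardize_covariates()] on the pooled
#'   unmatched sample.
#' @param area_stop logical; disable to let the greedy loop run until no
#'   merge improves the distance (used by the exhaustive-search oracle).
#' @return object of class `agglomerate`: list with `target_id`,
#'   `member_ids` (in merge order), `merged` (named list of merged summable,
#'   non-summable and outcome values), and `trace` (`step_distances`,
#'   `stop_reason`).
#' @export
build_agglomerate <- function(target, candidates, schema = covariate_schema(),
                              scaler, area_stop = TRUE) {
  if (NROW(candidates) == 0L) stop("empty candidate list for territory ",
                                   target$territory_id)
  ns <- schema$non_summable
  dv <- schema$distance_vars
  a <- as.numeric(candidates$area_ha)
  X <- as.matrix(candidates[, ns, drop = FALSE])
  cid <- candidates$territory_id
  mu <- scaler$mean[dv]; sdv <- scaler$sd[dv]
  tgt <- c(area_ha = as.numeric(target$area_ha),
           vapply(ns, function(f) as.numeric(target[[f]]), 0))
  t_area <- tgt[1L]

  A <- 0; xC <- numeric(length(ns))
  members <- integer(0)
  remaining <- seq_along(a)
  cur_dist <- Inf
  step_distances <- numeric(0)
  stop_reason <- "candidates_exhausted"

  repeat {
    if (!length(remaining)) { stop_reason <- "candidates_exhausted"; break }
    ar <- a[remaining]
    Anew <- A + ar
    # provisional area-weighted merge of every remaining candidate at once
    Xnew <- (matrix(A * xC, length(remaining), length(ns), byrow = TRUE) +
               ar * X[remaining, , drop = FALSE]) / Anew
    Z <- cbind(Anew, Xnew)
    d2 <- rowSums(sweep(sweep(Z, 2, tgt), 2, sdv, "/")^2)
    dmin <- min(d2)
    best <- which(d2 == dmin)
    if (length(best) > 1L) best <- best[which.min(cid[remaining[best]])]
    dist_best <- sqrt(dmin)
    if (length(members) && dist_best >= cur_dist) {
      stop_reason <- "no_improvement"; break
    }
    j <- remaining[best]
    A <- Anew[best]; xC <- Xnew[best, ]
    members <- c(members, j)
    remaining <- remaining[remaining != j]
    cur_dist <- dist_best
    step_distances <- c(step_distances, dist_best)
    if (area_stop && A > t_area) { stop_reason <- "area_exceeded"; break }
  }

  merged <- c(list(area_ha = A), as.list(stats::setNames(xC, ns)))
  for (f in schema$outcomes)
    merged[[f]] <- sum(as.numeric(candidates[[f]])[members])
  structure(list(target_id = target$territory_id,
                 member_ids = cid[members],
                 merged = merged,
                 trace = list(step_distances = step_distances,
                              stop_reason = stop_reason)),
            class = "agglomerate")
}

#' @export
print.agglomerate <- function(x, ...) {
  cat("Agglomerate for treatment territory", x$target_id, "\n",
      length(x$member_ids), "members, area",
      format(x$merged$area_ha, digits = 6), "ha, final distance",
      format(utils::tail(x$trace$step_distances, 1), digits = 4),
      paste0("(", x$trace$stop_reason, ")"), "\n")
  invisible(x)
}

#' One run of agglomerative matching
#'
#' Standardizes the pooled sample, builds the ANN index over the control
#' pool's non-summable covariates, queries a candidate list of size `K` for
#' each treatment territory and grows its agglomerate with
#' [build_agglomerate()].  No treatment territory is ever dropped; control
#' territories may appear in the agglomerates of several treatment units
#' within a run (reuse is permitted and auditable through `member_ids`).
#'
#' @param treatments,controls data.frames of territory records with disjoint
#'   `territory_id` sets.
#' @param schema a [covariate_schema()].
#' @param config a [match_config()].
#' @param seed seed for this run (default `config$seed`).
#' @param run_id identifier stored in the result.
#' @param scaler optional frozen scaler; computed on the pooled sample when
#'   omitted.
#' @return object of class `matched_set`: `pairs` (list of
#'   [build_agglomerate()] results, one per treatment unit), `merged`
#'   (data.frame of agglomerate records with `target_id`), `scaler`,
#'   `run_id`, `seed`, `n_treated`, `n_control`.
#' @export
run_matching <- function(treatments, controls, schema = covariate_schema(),
                         config = match_config(), seed = config$seed,
                         run_id = 1L, scaler = NULL) {
  if (length(intersect(treatments$territory_id, controls$territory_id)))
    stop("treatment and control territory_id sets must be disjoint")
  if (is.null(scaler)) scaler <- .make_scaler(treatments, controls, schema, config)
  zc <- standardize_covariates(controls, schema, vars = schema$ann_vars,
                               scaler = scaler)$z
  idx <- ann_index(zc, ids = seq_len(nrow(controls)),
                   n_trees = config$ann_trees,
                   leaf_size = config$ann_leaf_size, seed = seed)
  K <- min(config$K, nrow(controls))
  pairs <- vector("list", nrow(treatments))
  for (i in seq_len(nrow(treatments))) {
    t_row <- treatments[i, ]
    qz <- .standardize_vec(as.list(t_row), scaler, schema$ann_vars)
    cand_rows <- ann_query(idx, qz, K, search_k = config$search_k)
    if (!length(cand_rows))
      stop("no candidate controls for treatment territory ", t_row$territory_id)
    pairs[[i]] <- build_agglomerate(t_row, controls[cand_rows, , drop = FALSE],
                                    schema, scaler)
  }
  names(pairs) <- as.character(treatments$territory_id)
  merged <- do.call(rbind, lapply(pairs, function(p)
    data.frame(target_id = p$target_id, n_members = length(p$member_ids),
               as.data.frame(p$merged))))
  rownames(merged) <- NULL
  structure(list(run_id = run_id, seed = seed, pairs = pairs, merged = merged,
                 scaler = scaler, n_treated = nrow(treatments),
                 n_control = nrow(controls)),
            class = "matched_set")
}

#' @export
print.matched_set <- function(x, ...) {
  fd <- vapply(x$pairs, function(p) utils::tail(p$trace$step_distances, 1), 0)
  cat("Matched set (run", x$run_id, ", seed", x$seed, "):",
      x$n_treated, "treatment territories over a pool of", x$n_control,
      "controls\n  members per agglomerate:",
      paste(range(vapply(x$pairs, function(p) length(p$member_ids), 0L)),
            collapse = "-"),
      "  final distances:", format(mean(fd), digits = 4), "(mean)\n")
  invisible(x)
}

#' Repeat agglomerative matching under derived seeds
#'
#' Runs [run_matching()] `config$n_runs` times, each run with a distinct seed
#' derived deterministically from the master seed, to quantify the stochastic
#' error introduced by the approximate nearest-neighbour search.  The scaler
#' is frozen once on the pooled sample and shared by all runs.
#'
#' @inheritParams run_matching
#' @return list of `matched_set`, one per run.
#' @export
repeat_matching <- function(treatments, controls, schema = covariate_schema(),
                            config = match_config()) {
  scaler <- .make_scaler(treatments, controls, schema, config)
  lapply(seq_len(config$n_runs), function(r)
    run_matching(treatments, controls, schema, config,
                 seed = derive_seed(config$seed, r), run_id = r,
                 scaler = scaler))
}
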