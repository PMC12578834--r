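## Optimal full matching via minimum-cost network flow.
##
## A full match partitions treated and control units into strata, each
## containing at least one unit of both groups, every stratum a "star"
## (either one treated with several controls or one control with several
## treated).  The objective — the total of within-stratum treated-control
## distances — makes this exactly the minimum-weight edge cover of the
## bipartite distance matrix.  The cover is computed by the classical
## reduction: solve a min-cost (possibly partial) matching on reduced
## costs d[i,j] - m_i - m_j (m_v = cheapest edge at v) with successive
## shortest paths, then attach every still-uncovered unit through its
## cheapest edge.

# min-cost matching on a cost matrix, augmenting only while the shortest
# source-sink path has negative cost; returns matched (row, col) pairs
.mcf_negative_matching <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  V <- n + m + 2L; s <- 1L; t <- V
  nf <- n + n * m + m                       # forward arc count
  from <- integer(2L * nf); to <- integer(2L * nf)
  cap <- numeric(2L * nf); cst <- numeric(2L * nf)
  put <- function(k, u, v, cp, cs) {
    from[k] <<- u; to[k] <<- v; cap[k] <<- cp; cst[k] <<- cs
    from[k + nf] <<- v; to[k + nf] <<- u; cap[k + nf] <<- 0; cst[k + nf] <<- -cs
  }
  for (i in seq_len(n)) put(i, s, 1L + i, 1, 0)
  k <- n
  for (i in seq_len(n)) for (j in seq_len(m)) {
    k <- k + 1L
    put(k, 1L + i, 1L + n + j, 1, cost[i, j])
  }
  for (j in seq_len(m)) put(n + n * m + j, 1L + n + j, t, 1, 0)

  repeat {
    dist <- rep(Inf, V); dist[s] <- 0
    parent <- integer(V)
    repeat {                                 # Bellman-Ford to fixpoint
      cand <- dist[from] + cst
      cand[cap <= 0] <- Inf
      o <- order(to, cand)
      sel <- o[!duplicated(to[o])]
      upd <- cand[sel] < dist[to[sel]] - 1e-12
      if (!any(upd)) break
      dist[to[sel][upd]] <- cand[sel][upd]
      parent[to[sel][upd]] <- sel[upd]
    }
    if (!is.finite(dist[t]) || dist[t] >= -1e-12) break
    v <- t
    while (v != s) {                         # augment one unit of flow
      a <- parent[v]
      cap[a] <- cap[a] - 1
      cap[if (a > nf) a - nf else a + nf] <-
        cap[if (a > nf) a - nf else a + nf] + 1
      v <- from[a]
    }
  }
  used <- which(cap[(n + 1L):(n + n * m)] <= 0) # forward row->col arcs at cap 0
  cbind(row = (used - 1L) %/% m + 1L, col = (used - 1L) %% m + 1L)
}

#' Optimal full matching of treated units to controls
#'
#' Computes the full match minimizing the total within-stratum
#' treated-control distance over a bipartite distance matrix, by
#' minimum-cost network flow (see file header for the reduction).  Every
#' treated and every control unit is placed in exactly one stratum; each
#' stratum holds one treated with one or more controls, or one control with
#' one or more treated.  Treated units receive weight 1; each control in a
#' stratum with \eqn{n_T} treated and \eqn{n_C} controls receives weight
#' \eqn{n_T / n_C}, the standard ATT full-matching weights.
#'
#' @param distance numeric matrix of pairwise distances, treated units in
#'   rows, control units in columns; row/column names are used as unit ids.
#' @param common_support logical; when `TRUE`, `z_treated`/`z_control` must
#'   be supplied and control units with any standardized covariate outside
#'   the treated group's observed range are discarded before matching.
#' @param z_treated,z_control standardized covariate matrices backing the
#'   common-support trim.
#' @return object of class `ofm_result`: `strata` data.frame (`unit_id`,
#'   `role`, `stratum`), `weights` (named by `unit_id`), `unit_id`, `pairs`
#'   data.frame of cover edges with distances, `total_distance`, and
#'   `n_discarded` controls trimmed for common support.
#' @export
optimal_full_match <- function(distance, common_support = FALSE,
                               z_treated = NULL, z_control = NULL) {
  d <- as.matrix(distance)
  if (any(!is.finite(d))) stop("all pairwise distances must be finite")
  if (is.null(rownames(d))) rownames(d) <- paste0("t", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- paste0("c", seq_len(ncol(d)))
  n_discarded <- 0L
  if (common_support) {
    if (is.null(z_treated) || is.null(z_control))
      stop("common_support = TRUE requires z_treated and z_control")
    lo <- apply(z_treated, 2, min); hi <- apply(z_treated, 2, max)
    keep <- apply(z_control, 1, function(z) all(z >= lo & z <= hi))
    n_discarded <- sum(!keep)
    if (!any(keep)) stop("no control units inside the region of common support")
    d <- d[, keep, drop = FALSE]
  }
  n <- nrow(d); m <- ncol(d)
  if (n < 1L || m < 1L) stop("need at least one treated and one control unit")

  m_row <- apply(d, 1, min); m_col <- apply(d, 2, min)
  reduced <- d - outer(m_row, rep(1, m)) - outer(rep(1, n), m_col)
  pairs <- .mcf_negative_matching(pmin(reduced, 0))
  pairs <- pairs[reduced[pairs] < -1e-12, , drop = FALSE]

  edges <- matrix(0L, 0, 2)
  if (nrow(pairs)) edges <- pairs
  for (i in setdiff(seq_len(n), edges[, 1]))
    edges <- rbind(edges, c(i, which.min(d[i, ])))
  for (j in setdiff(seq_len(m), edges[, 2]))
    edges <- rbind(edges, c(which.min(d[, j]), j))

  # prune redundant edges (both endpoints of degree > 1, possible only
  # through ties/zero distances) so every component is a star
  repeat {
    degr <- tabulate(edges[, 1], n); degc <- tabulate(edges[, 2], m)
    red <- which(degr[edges[, 1]] > 1L & degc[edges[, 2]] > 1L)
    if (!length(red)) break
    edges <- edges[-red[which.max(d[edges[red, , drop = FALSE]])], , drop = FALSE]
  }

  # strata = connected components of the cover (each a star)
  comp <- seq_len(n + m)
  find <- function(x) { while (comp[x] != x) x <- comp[x] <- comp[comp[x]]; x }
  for (e in seq_len(nrow(edges)))
    comp[find(edges[e, 1])] <- find(edges[e, 2] + n)
  root <- vapply(seq_len(n + m), find, 0L)
  stratum <- match(root, unique(root))
  unit_id <- c(rownames(d), colnames(d))
  role <- rep(c("treated", "control"), c(n, m))
  nt <- tapply(role == "treated", stratum, sum)
  nc <- tapply(role == "control", stratum, sum)
  w <- ifelse(role == "treated", 1,
              as.numeric(nt[stratum] / nc[stratum]))
  structure(list(strata = data.frame(unit_id = unit_id, role = role,
                                     stratum = as.integer(stratum)),
                 weights = stats::setNames(w, unit_id),
                 unit_id = unit_id,
                 pairs = data.frame(treated_id = rownames(d)[edges[, 1]],
                                    control_id = colnames(d)[edges[, 2]],
                                    distance = d[edges]),
                 total_distance = sum(d[edges]),
                 n_discarded = n_discarded),
            class = "ofm_result")
}

#' @export
print.ofm_result <- function(x, ...) {
  cat("Optimal full match:", length(unique(x$strata$stratum)), "strata over",
      sum(x$strata$role == "treated"), "treated /",
      sum(x$strata$role == "control"), "control units; total distance",
      format(x$total_distance, digits = 6), "\n")
  if (x$n_discarded) cat("  (", x$n_discarded,
                         "controls discarded outside common support )\n")
  invisible(x)
}
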