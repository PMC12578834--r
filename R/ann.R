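## Approximate nearest neighbours via a forest of random-projection trees.
## Each tree recursively splits the point set by a hyperplane through the
## midpoint of two randomly chosen points; queries descend the forest
## best-first by hyperplane margin and collect leaf points until enough
## candidates are gathered, then rank them by exact Euclidean distance.
## The search is approximate by construction; rebuilding the index under a
## different seed yields a different (seeded, reproducible) candidate set,
## which is the stochastic component that repeated matching runs quantify.

# evaluate `expr` under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.rp_build_node <- function(x, idx, leaf_size) {
  n <- length(idx)
  if (n <= leaf_size) return(list(leaf = TRUE, idx = idx))
  pq <- sample(idx, 2L)
  w <- x[pq[1L], ] - x[pq[2L], ]
  if (all(w == 0)) w <- stats::rnorm(ncol(x))
  b <- sum(w * (x[pq[1L], ] + x[pq[2L], ]) / 2)
  proj <- as.numeric(x[idx, , drop = FALSE] %*% w)
  left <- proj < b
  if (all(left) || !any(left)) {        # degenerate hyperplane: median split
    b <- stats::median(proj)
    left <- proj < b
    if (all(left) || !any(left)) left <- seq_len(n) <= n %/% 2
  }
  list(leaf = FALSE, w = w, b = b,
       left = .rp_build_node(x, idx[left], leaf_size),
       right = .rp_build_node(x, idx[!left], leaf_size))
}

#' Build an approximate nearest-neighbour index over control units
#'
#' Constructs a forest of random-projection trees over the rows of a
#' standardized covariate matrix (by convention the *non-summable* covariates
#' of the control pool).  Queries against the index return approximately the
#' `k` nearest rows in Euclidean distance.  The forest is random; a fixed
#' `seed` makes it reproducible.
#'
#' @param x numeric matrix, one row per control unit (standardized).
#' @param ids vector of unit identifiers, one per row of `x`.
#' @param n_trees number of trees in the forest.
#' @param leaf_size maximum number of points held in a leaf.
#' @param seed RNG seed for tree construction (NULL: use current stream).
#' @return object of class `ann_index`.
#' @export
ann_index <- function(x, ids = seq_len(nrow(x)), n_trees = 10L,
                      leaf_size = 32L, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("cannot build an index over an empty control pool")
  if (length(ids) != nrow(x)) stop("ids must match rows of x")
  trees <- .with_seed(seed, lapply(seq_len(n_trees), function(i)
    .rp_build_node(x, seq_len(nrow(x)), leaf_size)))
  structure(list(x = x, ids = ids, trees = trees, n = nrow(x)),
            class = "ann_index")
}

#' Query an approximate nearest-neighbour index
#'
#' Best-first traversal of the forest by hyperplane margin, collecting leaf
#' candidates until at least `search_k` points (default `2 * k`) are seen,
#' then exact re-ranking of the candidate set.
#'
#' @param index an [ann_index()].
#' @param q numeric query vector on the same standardized scale as the index.
#' @param k number of neighbours requested; at most `index$n` are returned.
#' @param search_k number of candidates to inspect before re-ranking; larger
#'   values trade speed for recall.
#' @return vector of unit ids, closest first, length `min(k, index$n)`.
#' @export
ann_query <- function(index, q, k, search_k = NULL) {
  q <- as.numeric(q)
  k <- min(k, index$n)
  if (is.null(search_k)) search_k <- max(2L * k, 64L)
  search_k <- min(search_k, index$n)

  nodes <- index$trees                 # frontier: node list + priorities
  prio <- rep(Inf, length(nodes))
  cand <- integer(0)
  while (length(nodes) && length(unique(cand)) < search_k) {
    i <- which.max(prio)
    node <- nodes[[i]]
    p <- prio[i]
    nodes[[i]] <- NULL
    prio <- prio[-i]
    if (node$leaf) {
      cand <- c(cand, node$idx)
    } else {
      m <- sum(node$w * q) - node$b
      near <- if (m < 0) node$left else node$right
      far <- if (m < 0) node$right else node$left
      nodes <- c(nodes, list(near, far))
      prio <- c(prio, p, min(p, abs(m)))
    }
  }
  cand <- unique(cand)
  d2 <- rowSums(sweep(index$x[cand, , drop = FALSE], 2, q)^2)
  index$ids[cand[order(d2)][seq_len(min(k, length(cand)))]]
}
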