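#' Hill-climbing structure search with BIC score
#'
#' Greedy score-based search over DAGs: starting from the whitelist-only
#' graph, every legal single-edge addition, deletion and reversal is
#' evaluated (respecting acyclicity, the blacklist, and protection of
#' whitelisted edges) and the best strictly-improving move (improvement
#' greater than `tol`) is applied, until a local optimum or `max_iter`
#' moves. Ties are broken deterministically: smallest from-index, then
#' to-index, then addition before deletion before reversal. Local scores
#' are cached and recomputed only for nodes whose parent set changed.
#'
#' With `restarts > 0`, additional climbs are started from random
#' constraint-respecting DAGs (random topological order, each legal edge
#' present with probability 1/2) and the best-scoring local optimum over
#' all climbs is kept. The default 0 performs a single deterministic
#' climb from the whitelist-only graph; greedy search can terminate in a
#' genuine local optimum (coordinated multi-edge rearrangements are
#' never single improving moves), which restarts escape with high
#' probability on small networks.
#'
#' @param data an [as_dataset()] or data.frame.
#' @param constraints optional [constraint_set()]; defaults to
#'   unconstrained.
#' @param restarts number of random restarts (default 0).
#' @param max_iter maximum number of applied moves per climb.
#' @param tol minimum score improvement to accept a move (default 1e-9);
#'   also the width within which competing moves count as exactly tied.
#' @param tie how to resolve exact score ties among best moves:
#'   `"lexicographic"` (deterministic; the default for single fits) keeps
#'   the first move in enumeration order, `"random"` draws uniformly
#'   among the tied moves. Ties arise between score-equivalent
#'   structures, where the data genuinely cannot distinguish
#'   orientations; [bootstrap_average()] uses `"random"` (seeded per
#'   replicate) so that equivalence-class direction probabilities
#'   estimate the chance level 1/2 instead of being funnelled into a
#'   fixed orientation.
#' @return a `bn_dag` with attributes `score` (total network score) and
#'   `trajectory` (score after each applied move).
#' @export
hill_climb <- function(data, constraints = NULL, restarts = 0,
                       max_iter = Inf, tol = 1e-9,
                       tie = c("lexicographic", "random")) {
  nodes <- names(data)
  cs <- constraints %||% constraint_set(nodes)
  stopifnot(setequal(cs$nodes, nodes))
  ctx <- make_score_context(data)
  hc_run(ctx, cs, restarts = restarts, max_iter = max_iter, tol = tol,
         tie = match.arg(tie))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hc_run <- function(ctx, cs, restarts = 0, max_iter = Inf, tol = 1e-9,
                   tie = c("lexicographic", "random")) {
  tie <- match.arg(tie)
  score_fn <- cached_scorer(ctx)
  best <- hc_climb(ctx, cs, whitelist_dag(cs)$amat, score_fn, max_iter, tol,
                   tie)
  r <- 0
  while (r < restarts) {
    start <- random_start_amat(cs)
    cand <- hc_climb(ctx, cs, start, score_fn, max_iter, tol, tie)
    if (attr(cand, "score") > attr(best, "score") + tol) best <- cand
    r <- r + 1
  }
  attr(best, "amat_raw") <- NULL
  best
}

# One greedy climb. Candidate moves are enumerated in the deterministic
# order (from-index, to-index, add < delete < reverse). Exact score ties
# among the best moves (within `tol`, the numerical width of score
# equivalence) are resolved per `tie`: "lexicographic" keeps the first
# enumerated move; "random" draws uniformly among the tied set, which the
# bootstrap uses so that score-equivalent orientations are not
# systematically funnelled into one direction.
hc_climb <- function(ctx, cs, amat, score_fn, max_iter, tol, tie) {
  nodes <- cs$nodes
  p <- length(nodes)
  cur <- vapply(seq_len(p), function(j)
    score_fn(nodes[j], nodes[amat[, j]]), numeric(1))
  trajectory <- sum(cur)
  iter <- 0
  repeat {
    ops <- integer(0); fs <- integer(0); ts <- integer(0); ds <- numeric(0)
    push <- function(op, f, t, delta) {
      if (delta > tol) {
        ops[[length(ops) + 1L]] <<- op
        fs[[length(fs) + 1L]] <<- f
        ts[[length(ts) + 1L]] <<- t
        ds[[length(ds) + 1L]] <<- delta
      }
    }
    for (f in seq_len(p)) for (t in seq_len(p)) {
      if (f == t) next
      # addition
      if (!amat[f, t] && !amat[t, f] && !cs$black[nodes[f], nodes[t]] &&
          !has_path(amat, t, f)) {
        push(1L, f, t,
             score_fn(nodes[t], nodes[c(which(amat[, t]), f)]) - cur[t])
      }
      if (amat[f, t] && !cs$white[nodes[f], nodes[t]]) {
        pa_t <- which(amat[, t]); pa_wo_f <- setdiff(pa_t, f)
        # deletion
        push(2L, f, t, score_fn(nodes[t], nodes[pa_wo_f]) - cur[t])
        # reversal
        if (!cs$black[nodes[t], nodes[f]]) {
          amat[f, t] <- FALSE
          ok <- !has_path(amat, f, t)
          amat[f, t] <- TRUE
          if (ok) {
            push(3L, f, t,
                 (score_fn(nodes[t], nodes[pa_wo_f]) - cur[t]) +
                   (score_fn(nodes[f], nodes[c(which(amat[, f]), t)]) - cur[f]))
          }
        }
      }
    }
    if (length(ds) == 0L || iter >= max_iter) break
    tied <- which(ds >= max(ds) - tol)
    pick <- if (tie == "random" && length(tied) > 1L)
      tied[sample.int(length(tied), 1L)] else tied[1L]
    op <- ops[pick]; f <- fs[pick]; t <- ts[pick]
    if (op == 1L) {
      amat[f, t] <- TRUE
      cur[t] <- score_fn(nodes[t], nodes[amat[, t]])
    } else if (op == 2L) {
      amat[f, t] <- FALSE
      cur[t] <- score_fn(nodes[t], nodes[amat[, t]])
    } else {
      amat[f, t] <- FALSE
      amat[t, f] <- TRUE
      cur[t] <- score_fn(nodes[t], nodes[amat[, t]])
      cur[f] <- score_fn(nodes[f], nodes[amat[, f]])
    }
    iter <- iter + 1
    trajectory <- c(trajectory, sum(cur))
  }
  dag <- structure(list(nodes = nodes, amat = amat), class = "bn_dag")
  attr(dag, "score") <- sum(cur)
  attr(dag, "trajectory") <- trajectory
  attr(dag, "amat_raw") <- amat
  dag
}

# random constraint-respecting starting DAG for restarts: whitelist
# edges plus each legal edge (oriented along a random topological order)
# with probability 1/2
random_start_amat <- function(cs) {
  nodes <- cs$nodes
  p <- length(nodes)
  amat <- cs$white
  ord <- sample.int(p)
  if (p >= 2L) for (i in 2:p) for (j in 1:(i - 1)) {
    f <- ord[j]; t <- ord[i]
    if (!amat[f, t] && !amat[t, f] && !cs$black[nodes[f], nodes[t]] &&
        stats::runif(1) < 0.5 && !has_path(amat, t, f))
      amat[f, t] <- TRUE
  }
  amat
}

#' Exhaustive structure search (test oracle)
#'
#' Enumerates every constraint-respecting DAG over at most 5 nodes (each
#' unordered pair is absent, forward or backward; cyclic assignments are
#' discarded) and returns the BIC-score maximizer. Ties are broken by the
#' canonical enumeration order of edge lists, so the result is
#' deterministic. Intended as an independent optimum against which the
#' hill-climbing search is validated on small problems; infeasible beyond
#' a handful of nodes, where greedy search is the only practical option.
#'
#' @inheritParams hill_climb
#' @return the optimal `bn_dag`, with attributes `score` and
#'   `n_enumerated` (number of DAGs satisfying the constraints).
#' @export
exhaustive_search <- function(data, constraints = NULL) {
  nodes <- names(data)
  p <- length(nodes)
  if (p > 5L) stop("exhaustive search is restricted to at most 5 nodes")
  cs <- constraints %||% constraint_set(nodes)
  stopifnot(setequal(cs$nodes, nodes))
  ctx <- make_score_context(data)
  score_fn <- cached_scorer(ctx)
  pairs <- if (p >= 2L) utils::combn(p, 2) else matrix(integer(0), 2, 0)
  npair <- ncol(pairs)
  # per-pair legal states: 0 none, 1 i->j, 2 j->i
  states <- vector("list", max(npair, 1L))
  for (k in seq_len(npair)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    st <- 0:2
    if (cs$black[nodes[i], nodes[j]]) st <- setdiff(st, 1L)
    if (cs$black[nodes[j], nodes[i]]) st <- setdiff(st, 2L)
    if (cs$white[nodes[i], nodes[j]]) st <- intersect(st, 1L)
    if (cs$white[nodes[j], nodes[i]]) st <- intersect(st, 2L)
    if (length(st) == 0L) stop("inconsistent constraints")
    states[[k]] <- st
  }
  grid <- if (npair > 0) as.matrix(expand.grid(rev(states),
                                               KEEP.OUT.ATTRS = FALSE))[,
                                   npair:1, drop = FALSE]
          else matrix(integer(0), 1, 0)
  best_score <- -Inf
  best_amat <- NULL
  n_enum <- 0L
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(grid))) {
    amat[] <- FALSE
    for (k in seq_len(npair)) {
      st <- grid[r, k]
      if (st == 1L) amat[pairs[1, k], pairs[2, k]] <- TRUE
      else if (st == 2L) amat[pairs[2, k], pairs[1, k]] <- TRUE
    }
    if (has_cycle(amat)) next
    n_enum <- n_enum + 1L
    total <- sum(vapply(seq_len(p), function(j)
      score_fn(nodes[j], nodes[amat[, j]]), numeric(1)))
    if (total > best_score) {
      best_score <- total
      best_amat <- amat
    }
  }
  dag <- structure(list(nodes = nodes, amat = best_amat), class = "bn_dag")
  attr(dag, "score") <- best_score
  attr(dag, "n_enumerated") <- n_enum
  dag
}
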