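#' Bootstrap-averaged Bayesian network
#'
#' Draws `B` nonparametric bootstrap resamples of the rows (with
#' replacement), learns the best-fit network on each with [hill_climb()]
#' under the given constraints, and counts, for every ordered node pair,
#' how often the directed edge appears among the B best-fit networks.
#' From these counts:
#'
#' * the *strength* of an undirected pair a-b is the fraction of networks
#'   containing a -> b or b -> a;
#' * the *direction probability* of a -> b is the fraction of those
#'   networks containing the pair in which the edge is oriented a -> b
#'   (i.e. conditional on existence).
#'
#' Replicate b uses seed `seed + b`, so replicates are independent,
#' order-invariant and could be computed concurrently with identical
#' results. A degenerate resample (any column constant after resampling)
#' is redrawn under a derived sub-seed rather than failing, so exactly B
#' completed replicates are always returned; the number of redraws is
#' recorded.
#'
#' @inheritParams hill_climb
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param restarts random restarts passed to each hill climb.
#' @return an `averaged_network`: list with `nodes`, `B`, `counts`
#'   (directed-edge count matrix), and `redraws`.
#' @export
bootstrap_average <- function(data, constraints = NULL, B = 1000, seed = 1,
                              restarts = 0) {
  stopifnot(B >= 1)
  nodes <- names(data)
  cs <- constraints %||% constraint_set(nodes)
  base <- make_score_context(data)
  n <- base$n
  counts <- matrix(0L, length(nodes), length(nodes),
                   dimnames = list(nodes, nodes))
  redraws <- 0L
  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      sub_seed <- (as.integer(seed) + b + attempt * 1000003L) %% 2147483647L
      set.seed(sub_seed)
      idx <- sample.int(n, n, replace = TRUE)
      ctx <- resample_context(base, idx)
      if (!context_degenerate(ctx)) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (attempt > 100L) stop("could not draw a non-degenerate resample")
    }
    dag <- hc_run(ctx, cs, restarts = restarts, tie = "random")
    counts <- counts + dag$amat
  }
  structure(list(nodes = nodes, B = as.integer(B), counts = counts,
                 redraws = redraws),
            class = "averaged_network")
}

resample_context <- function(base, idx) {
  if (base$type == "gaussian") {
    mi <- base$m[idx, , drop = FALSE]
    s <- crossprod(sweep(mi, 2, colMeans(mi)))
    dimnames(s) <- list(base$nodes, base$nodes)
    list(type = "gaussian", n = length(idx), nodes = base$nodes, s = s)
  } else {
    list(type = "multinomial", n = length(idx), nodes = base$nodes,
         codes = base$codes[idx, , drop = FALSE], nlev = base$nlev)
  }
}

context_degenerate <- function(ctx) {
  if (ctx$type == "gaussian") {
    any(diag(ctx$s) <= 0)
  } else {
    any(vapply(ctx$nodes, function(v)
      length(unique(ctx$codes[, v])) < 2L, logical(1)))
  }
}

#' Edge strength / existence probability of an averaged network
#'
#' @param net an `averaged_network`.
#' @param a,b node names.
#' @return `edge_strength`: fraction of bootstrap networks containing the
#'   a-b edge in either orientation. `edge_direction`: fraction of those
#'   networks in which it is oriented a -> b (NA if the pair never
#'   appears). `edge_probability`: fraction of all bootstrap networks
#'   containing the directed edge a -> b (strength times direction).
#' @export
edge_strength <- function(net, a, b) {
  (net$counts[a, b] + net$counts[b, a]) / net$B
}

#' @rdname edge_strength
#' @export
edge_direction <- function(net, a, b) {
  tot <- net$counts[a, b] + net$counts[b, a]
  if (tot == 0) return(NA_real_)
  net$counts[a, b] / tot
}

#' @rdname edge_strength
#' @export
edge_probability <- function(net, a, b) {
  net$counts[a, b] / net$B
}

#' Significance threshold for averaged-network edges
#'
#' Estimates which edges are "sufficiently strong" to retain: the
#' empirical CDF of the observed pairwise strengths is compared against
#' the ideal degenerate CDF in which every arc has strength exactly 0
#' (noise) or exactly 1 (real), and the inclusion threshold is the
#' observed strength value minimizing the L1 distance between the two
#' CDFs (Scutari's averaged-network criterion), found by brute-force
#' search over the observed strength values.
#'
#' @param net an `averaged_network`.
#' @return the threshold (numeric scalar in \[0, 1\]).
#' @export
edge_strength_threshold <- function(net) {
  s <- pair_strengths(net)
  l1_threshold(s)
}

pair_strengths <- function(net) {
  p <- length(net$nodes)
  if (p < 2L) return(numeric(0))
  pr <- utils::combn(p, 2)
  (net$counts[t(pr)] + net$counts[t(pr[2:1, , drop = FALSE])]) / net$B
}

# exact L1 distance between ecdf of s and the two-point ideal CDF whose
# noise fraction is the fraction of strengths below the candidate cut
l1_threshold <- function(s) {
  if (length(s) == 0L) return(1)
  cands <- sort(unique(s))
  knots <- sort(unique(c(0, s, 1)))
  widths <- diff(knots)
  lefts <- knots[-length(knots)]
  fhat <- vapply(lefts, function(x) mean(s <= x), numeric(1))
  best <- Inf
  best_c <- cands[1]
  for (cc in cands) {
    q <- mean(s < cc)
    d <- sum(abs(fhat - q) * widths)
    if (d < best - 1e-12) {
      best <- d
      best_c <- cc
    }
  }
  best_c
}

#' Thresholded averaged network as an edge table
#'
#' Keeps the pairs whose strength reaches the threshold (estimated by
#' [edge_strength_threshold()] when not supplied) and orients each by its
#' majority direction. An exact 0.5 direction split is broken towards the
#' canonical node order and flagged ambiguous.
#'
#' @param net an `averaged_network`.
#' @param threshold optional inclusion threshold in \[0, 1\].
#' @return data.frame with columns `from`, `to`, `strength`,
#'   `direction_prob`, `ambiguous`.
#' @export
averaged_dag <- function(net, threshold = NULL) {
  threshold <- threshold %||% edge_strength_threshold(net)
  stopifnot(threshold >= 0, threshold <= 1)
  nodes <- net$nodes
  p <- length(nodes)
  rows <- list()
  if (p >= 2L) for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    a <- nodes[i]; b <- nodes[j]
    str <- edge_strength(net, a, b)
    if (str <= 0 || str < threshold) next
    dir_ab <- edge_direction(net, a, b)
    if (dir_ab >= 0.5) {
      rows[[length(rows) + 1L]] <- data.frame(
        from = a, to = b, strength = str, direction_prob = dir_ab,
        ambiguous = dir_ab == 0.5, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        from = b, to = a, strength = str, direction_prob = 1 - dir_ab,
        ambiguous = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      strength = numeric(0), direction_prob = numeric(0),
                      ambiguous = logical(0)))
  do.call(rbind, rows)
}
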