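#' Directed acyclic graphs over named nodes
#'
#' A DAG is stored as a logical adjacency matrix (`amat[i, j]` is TRUE for
#' an edge i -> j) with node names on both dimensions. Construction checks
#' acyclicity, and rejects self-loops and duplicate edges.
#'
#' @param nodes character vector of node names.
#' @param edges optional two-column matrix or data.frame of (from, to)
#'   edges.
#' @return a `bn_dag` object.
#' @export
empty_dag <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  p <- length(nodes)
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  dag <- structure(list(nodes = nodes, amat = amat), class = "bn_dag")
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    for (k in seq_len(nrow(edges)))
      dag <- add_edge(dag, edges[k, 1], edges[k, 2])
  }
  dag
}

#' @rdname empty_dag
#' @param dag a `bn_dag`.
#' @param from,to node names.
#' @export
add_edge <- function(dag, from, to) {
  stopifnot(from %in% dag$nodes, to %in% dag$nodes)
  if (from == to) stop("self edges are not allowed")
  if (dag$amat[from, to]) stop("duplicate edge ", from, " -> ", to)
  dag$amat[from, to] <- TRUE
  if (has_cycle(dag$amat)) stop("edge ", from, " -> ", to, " creates a cycle")
  dag
}

#' @rdname empty_dag
#' @export
dag_edges <- function(dag) {
  idx <- which(dag$amat, arr.ind = TRUE)
  data.frame(from = dag$nodes[idx[, 1]], to = dag$nodes[idx[, 2]],
             stringsAsFactors = FALSE)[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' @rdname empty_dag
#' @param node a node name.
#' @export
dag_parents <- function(dag, node) {
  dag$nodes[dag$amat[, node]]
}

# cycle test on a logical adjacency matrix by repeated leaf-stripping
has_cycle <- function(amat) {
  p <- nrow(amat)
  keep <- rep(TRUE, p)
  repeat {
    outdeg <- rowSums(amat[keep, keep, drop = FALSE])
    sinks <- which(outdeg == 0)
    if (length(sinks) == 0L) return(any(keep))
    keep[which(keep)[sinks]] <- FALSE
    if (!any(keep)) return(FALSE)
  }
}

# TRUE if a directed path from -> ... -> to exists
has_path <- function(amat, from, to) {
  if (from == to) return(TRUE)
  frontier <- from
  seen <- rep(FALSE, nrow(amat))
  while (length(frontier)) {
    seen[frontier] <- TRUE
    nxt <- which(colSums(amat[frontier, , drop = FALSE]) > 0)
    if (to %in% nxt) return(TRUE)
    frontier <- nxt[!seen[nxt]]
  }
  FALSE
}

#' Edge constraints encoding directional anchors
#'
#' A constraint set over a fixed node universe holds a blacklist of
#' forbidden directed edges and a whitelist of required directed edges.
#' The helpers encode the two anchor idioms used with genetic
#' instruments:
#'
#' * [no_incoming()] - arrows are constrained to come out from (rather
#'   than go into) the anchor nodes: every edge into an anchor is
#'   blacklisted;
#' * [no_children()] - the node may have no child nodes: every edge out
#'   of it is blacklisted;
#' * [single_outgoing()] - an allele-score node must have one and only
#'   one edge, going from itself to its instrumented variable: that edge
#'   is whitelisted and every other edge incident to the score node is
#'   blacklisted.
#'
#' @param nodes node universe (character).
#' @param blacklist,whitelist optional two-column (from, to) matrices or
#'   data.frames.
#' @return a `constraint_set` with logical matrices `black` and `white`.
#' @export
constraint_set <- function(nodes, blacklist = NULL, whitelist = NULL) {
  p <- length(nodes)
  black <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  white <- black
  fill <- function(m, pairs) {
    if (!is.null(pairs) && NROW(pairs) > 0) {
      pairs <- as.matrix(pairs)
      for (k in seq_len(nrow(pairs))) m[pairs[k, 1], pairs[k, 2]] <- TRUE
    }
    m
  }
  black <- fill(black, blacklist)
  white <- fill(white, whitelist)
  diag(black) <- TRUE
  cs <- structure(list(nodes = nodes, black = black, white = white),
                  class = "constraint_set")
  validate_constraints(cs)
  cs
}

validate_constraints <- function(cs) {
  overlap <- cs$white & cs$black
  if (any(overlap)) stop("whitelist and blacklist overlap")
  if (has_cycle(cs$white)) stop("whitelist is cyclic")
  invisible(cs)
}

#' @rdname constraint_set
#' @param cs a `constraint_set`.
#' @param anchors nodes constrained to have only outgoing edges.
#' @export
no_incoming <- function(cs, anchors) {
  stopifnot(all(anchors %in% cs$nodes))
  cs$black[, anchors] <- TRUE
  diag(cs$black) <- TRUE
  validate_constraints(cs)
  cs
}

#' @rdname constraint_set
#' @param node node constrained to have no child nodes.
#' @export
no_children <- function(cs, node) {
  stopifnot(all(node %in% cs$nodes))
  cs$black[node, ] <- TRUE
  diag(cs$black) <- TRUE
  validate_constraints(cs)
  cs
}

#' @rdname constraint_set
#' @param score score (anchor) node; `target` its instrumented variable.
#' @param target node the whitelisted edge points to.
#' @export
single_outgoing <- function(cs, score, target) {
  stopifnot(score %in% cs$nodes, target %in% cs$nodes, score != target)
  cs$black[score, ] <- TRUE
  cs$black[, score] <- TRUE
  cs$black[score, target] <- FALSE
  cs$white[score, target] <- TRUE
  validate_constraints(cs)
  cs
}

# the DAG every search starts from: whitelist edges only
whitelist_dag <- function(cs) {
  dag <- structure(list(nodes = cs$nodes, amat = cs$white), class = "bn_dag")
  if (has_cycle(dag$amat)) stop("whitelist is cyclic")
  dag
}
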