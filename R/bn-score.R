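#' Decomposable BIC network score
#'
#' Local (per-node) BIC scores on the "higher is better" scale:
#' maximized log-likelihood of the node given its parents minus
#' `(d / 2) * log(n)` where d is the number of free parameters. The
#' network score of a DAG is the exact sum of its local scores
#' (decomposability), so this sign convention matches the usual reporting
#' of average network scores as penalized log-likelihoods.
#'
#' * Gaussian node: the node is regressed on its parents (intercept
#'   included); the maximized log-likelihood uses the MLE residual
#'   variance (divisor n, floored at 1e-12 to guard degenerate bootstrap
#'   columns); d = #parents + 2 (intercept, slopes, residual variance).
#' * Multinomial node with L levels: sum over parent configurations j of
#'   `n_jk * log(n_jk / n_j)`; zero counts contribute 0;
#'   d = (L - 1) * prod(parent levels).
#'
#' Networks must be homogeneous: all nodes Gaussian or all multinomial
#' (each simulation study declares a single treatment for all its
#' variables; mixed networks are not supported).
#'
#' @param node node (column) name.
#' @param parents character vector of parent names (possibly empty).
#' @param data an [as_dataset()] or data.frame (kinds taken from the data
#'   set, defaulting to continuous).
#' @return the local score (numeric scalar).
#' @export
bic_local_score <- function(node, parents = character(0), data) {
  ctx <- make_score_context(data)
  local_score(ctx, node, parents)
}

#' @rdname bic_local_score
#' @param dag a `bn_dag` whose nodes are a subset of the data set's
#'   variables.
#' @return `network_score` returns a list with `total`, `per_node` and `n`.
#' @export
network_score <- function(dag, data) {
  ctx <- make_score_context(data)
  per_node <- vapply(dag$nodes, function(v)
    local_score(ctx, v, dag_parents(dag, v)), numeric(1))
  list(total = sum(per_node), per_node = per_node, n = ctx$n)
}

# Precomputed sufficient statistics for fast repeated local scoring.
# Gaussian: centered cross-product matrix; multinomial: 1-based integer
# codes and level counts.
make_score_context <- function(data, nodes = names(data)) {
  if (nrow(data) == 0L) stop("empty data")
  kind <- dataset_kind(data)[nodes]
  x <- as.data.frame(data)[, nodes, drop = FALSE]
  n <- nrow(x)
  if (all(kind == "continuous")) {
    m <- as.matrix(x)
    s <- crossprod(sweep(m, 2, colMeans(m)))
    dimnames(s) <- list(nodes, nodes)
    list(type = "gaussian", n = n, nodes = nodes, s = s, m = m)
  } else if (all(kind == "categorical")) {
    lev <- dataset_levels(data)[nodes]
    codes <- matrix(0L, n, length(nodes), dimnames = list(NULL, nodes))
    for (v in nodes) codes[, v] <- match(x[[v]], lev[[v]])
    list(type = "multinomial", n = n, nodes = nodes, codes = codes,
         nlev = vapply(lev, length, integer(1)))
  } else {
    stop("mixed continuous/categorical networks are not supported")
  }
}

local_score <- function(ctx, node, parents) {
  if (ctx$type == "gaussian") local_score_gaussian(ctx, node, parents)
  else local_score_multinomial(ctx, node, parents)
}

local_score_gaussian <- function(ctx, node, parents) {
  n <- ctx$n
  syy <- ctx$s[node, node]
  if (length(parents)) {
    spp <- ctx$s[parents, parents, drop = FALSE]
    spy <- ctx$s[parents, node]
    # projection onto the parent column space via a pseudo-inverse, so
    # exactly collinear parents (duplicated bootstrap columns) only pay
    # the dimension penalty instead of failing
    ev <- eigen(spp, symmetric = TRUE)
    keep <- ev$values > max(ev$values, 0) * 1e-10
    if (any(keep)) {
      u <- crossprod(ev$vectors[, keep, drop = FALSE], spy)
      syy <- syy - sum(u^2 / ev$values[keep])
    }
  }
  sigma2 <- max(syy / n, 1e-12)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  d <- length(parents) + 2
  unname(ll - d / 2 * log(n))
}

local_score_multinomial <- function(ctx, node, parents) {
  n <- ctx$n
  l <- ctx$nlev[node]
  if (length(parents)) {
    strides <- cumprod(c(1, ctx$nlev[parents]))
    ncfg <- strides[length(strides)]
    cfg <- 1L
    for (k in seq_along(parents))
      cfg <- cfg + (ctx$codes[, parents[k]] - 1L) * as.integer(strides[k])
  } else {
    ncfg <- 1L
    cfg <- rep(1L, n)
  }
  counts <- matrix(tabulate(cfg + (ctx$codes[, node] - 1L) * as.integer(ncfg),
                            nbins = ncfg * l), ncfg, l)
  rowtot <- rowSums(counts)
  nz <- counts > 0
  ll <- sum(counts[nz] * log(counts[nz] / rowtot[row(counts)[nz]]))
  d <- (l - 1) * ncfg
  unname(ll - d / 2 * log(n))
}

# local-score cache shared by one search; key = node | sorted parent set
cached_scorer <- function(ctx) {
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  function(node, parents) {
    key <- paste0(node, "|", paste(sort(parents), collapse = ","))
    val <- cache[[key]]
    if (is.null(val)) {
      val <- local_score(ctx, node, parents)
      cache[[key]] <- val
    }
    val
  }
}
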