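#' Two-stage least squares Mendelian randomization
#'
#' Estimates the causal effect of `exposure` on `outcome` using one or more
#' genetic `instruments`. Stage one regresses the exposure on the
#' instruments (with intercept); stage two regresses the outcome on the
#' predicted exposure. The point estimate is identical in both modes; only
#' the standard error (and hence the p-value) differs:
#'
#' * `correct_first_stage = TRUE` (instrumental-variable convention, as in
#'   `ivreg`-style IV regression): the residual variance is computed from
#'   the outcome minus the fitted structural equation evaluated at the
#'   *observed* exposure, accounting for first-stage uncertainty;
#' * `correct_first_stage = FALSE` ("MR prime"): the naive second-stage OLS
#'   residuals are used. For a single instrument this gives a p-value
#'   identical (to machine precision) to simply regressing the outcome on
#'   the instrument.
#'
#' p-values are two-sided from a t distribution with n - 2 residual
#' degrees of freedom.
#'
#' @param data an [as_dataset()] or data.frame.
#' @param exposure,outcome column names.
#' @param instruments character vector of instrument column names.
#' @param correct_first_stage logical; see above.
#' @return an `mr_result` list with fields `estimate`, `se`, `p_value`,
#'   `df`, `instruments`, `first_stage_p` (per-instrument coefficient
#'   p-values from the joint first-stage regression), and `mode`.
#' @export
fit_2sls <- function(data, exposure, outcome, instruments,
                     correct_first_stage = TRUE) {
  stopifnot(length(instruments) >= 1L,
            all(c(exposure, outcome, instruments) %in% names(data)))
  x <- data[[exposure]]
  y <- data[[outcome]]
  n <- length(x)
  if (n <= length(instruments) + 2L)
    stop("too few observations for the number of instruments")
  zmat <- as.matrix(as.data.frame(data)[, instruments, drop = FALSE])
  if (any(apply(zmat, 2, stats::sd) == 0) || stats::sd(x) == 0)
    stop("zero-variance instrument or exposure")
  stage1 <- stats::lm(x ~ zmat)
  if (any(is.na(stats::coef(stage1))))
    stop("perfect collinearity among instruments")
  xhat <- stats::fitted(stage1)
  s1 <- summary(stage1)$coefficients
  first_stage_p <- stats::setNames(s1[-1, 4], instruments)
  stage2 <- stats::lm(y ~ xhat)
  est <- unname(stats::coef(stage2)[2])
  df <- n - 2L
  ssx <- sum((xhat - mean(xhat))^2)
  if (correct_first_stage) {
    resid_iv <- y - (stats::coef(stage2)[1] + est * x)
    sigma2 <- sum(resid_iv^2) / df
  } else {
    sigma2 <- sum(stats::residuals(stage2)^2) / df
  }
  se <- sqrt(sigma2 / ssx)
  tval <- est / se
  structure(list(estimate = est, se = se,
                 p_value = 2 * stats::pt(-abs(tval), df),
                 df = df, instruments = instruments,
                 first_stage_p = first_stage_p,
                 mode = if (correct_first_stage) "corrected" else "uncorrected",
                 exposure = exposure, outcome = outcome,
                 detected = NA),
            class = "mr_result")
}

#' Weighted allele score
#'
#' Builds a composite genetic instrument for `target`: unless external
#' `weights` are supplied, each SNP is regressed marginally on the target,
#' SNPs with marginal p below `selection_threshold` are selected, and the
#' score is the weighted sum of allele counts using the estimated
#' regression coefficients as weights. An empty selection yields a flagged
#' invalid score (all-zero values, `valid = FALSE`) rather than an error,
#' so replicate loops stay alive.
#'
#' @param genotypes data.frame or matrix of 0/1/2-coded SNP columns.
#' @param target numeric vector (the instrumented trait).
#' @param weights optional externally estimated per-SNP weights (named or
#'   in column order); when given, all SNPs are used with these weights
#'   and no selection is performed.
#' @param selection_threshold marginal p-value threshold (default 5e-6).
#' @return an `allele_score` list with `score`, `snps`, `weights`,
#'   `selection_threshold`, `p_values` and `valid`.
#' @export
build_allele_score <- function(genotypes, target, weights = NULL,
                               selection_threshold = 5e-6) {
  g <- as.matrix(as.data.frame(genotypes))
  n <- nrow(g)
  stopifnot(length(target) == n)
  if (!is.null(weights)) {
    stopifnot(length(weights) == ncol(g))
    w <- if (!is.null(names(weights))) weights[colnames(g)] else weights
    return(structure(list(score = drop(g %*% w), snps = colnames(g),
                          weights = stats::setNames(w, colnames(g)),
                          selection_threshold = NA_real_,
                          p_values = NULL, valid = TRUE),
                     class = "allele_score"))
  }
  mm <- marginal_regressions(g, target)
  sel <- which(mm$p < selection_threshold)
  if (length(sel) == 0L) {
    return(structure(list(score = rep(0, n), snps = character(0),
                          weights = numeric(0),
                          selection_threshold = selection_threshold,
                          p_values = mm$p, valid = FALSE),
                     class = "allele_score"))
  }
  w <- mm$beta[sel]
  structure(list(score = drop(g[, sel, drop = FALSE] %*% w),
                 snps = colnames(g)[sel],
                 weights = stats::setNames(w, colnames(g)[sel]),
                 selection_threshold = selection_threshold,
                 p_values = mm$p, valid = TRUE),
            class = "allele_score")
}

# vectorized simple linear regressions of target on each column of g
# (slope, t-based two-sided p with n - 2 df)
marginal_regressions <- function(g, target) {
  n <- length(target)
  gc <- sweep(g, 2, colMeans(g))
  tc <- target - mean(target)
  sxx <- colSums(gc^2)
  sxy <- drop(crossprod(gc, tc))
  syy <- sum(tc^2)
  beta <- ifelse(sxx > 0, sxy / sxx, 0)
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / pmax(sxx, .Machine$double.xmin))
  tval <- ifelse(se > 0, beta / se, 0)
  p <- 2 * stats::pt(-abs(tval), n - 2)
  p[sxx == 0] <- 1
  list(beta = beta, p = p)
}
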