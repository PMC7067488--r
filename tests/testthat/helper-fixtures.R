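# shared fixture builders and independent oracles

# random linear-SEM data set over p continuous variables: random causal
# order, each upstream pair linked with probability eprob, coefficients
# uniform +/-[lo, hi], unit residual SD
rand_sem_data <- function(p, n, seed, eprob = 0.5, lo = 0, hi = 1) {
  set.seed(seed)
  ord <- sample(p)
  b <- matrix(0, p, p)
  if (p >= 2) for (i in 2:p) for (j in 1:(i - 1))
    if (runif(1) < eprob)
      b[ord[j], ord[i]] <- sample(c(-1, 1), 1) * runif(1, lo, hi)
  x <- matrix(0, n, p)
  for (i in 1:p) x[, ord[i]] <- x %*% b[, ord[i]] + rnorm(n)
  colnames(x) <- paste0("V", 1:p)
  as_dataset(as.data.frame(x))
}

# independent re-derivation of the dependent-correlations Z test
# (Fisher transforms; correlations share one variable)
steiger_z_oracle <- function(g, a, b) {
  n <- length(g)
  r1 <- cor(g, a); r2 <- cor(g, b); r12 <- cor(a, b)
  z1 <- 0.5 * log((1 + r1) / (1 - r1))
  z2 <- 0.5 * log((1 + r2) / (1 - r2))
  rbar2 <- (r1^2 + r2^2) / 2
  f <- (1 - r12) / (2 * (1 - rbar2))
  if (f > 1) f <- 1
  h <- (1 - f * rbar2) / (1 - rbar2)
  zstat <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  list(z = zstat, p = 2 * pnorm(-abs(zstat)))
}

# direct log-density evaluation of a Gaussian node given parents:
# OLS by normal equations on the raw design, then per-row dnorm sums
gaussian_local_oracle <- function(y, xmat, n_penalty_params = NULL) {
  n <- length(y)
  design <- if (is.null(xmat)) matrix(1, n, 1) else cbind(1, xmat)
  beta <- solve(t(design) %*% design, t(design) %*% y)
  resid <- y - design %*% beta
  sigma2 <- sum(resid^2) / n
  ll <- sum(dnorm(y, design %*% beta, sqrt(sigma2), log = TRUE))
  d <- if (is.null(n_penalty_params)) ncol(design) + 1 else n_penalty_params
  ll - d / 2 * log(n)
}
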