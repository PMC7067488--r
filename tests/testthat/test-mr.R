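test_that("uncorrected 2SLS p-value equals the reduced-form regression p", {
  for (model in 1:3) {
    d <- simulate_study1(study1_params(model = model, beta_xy = 0.3,
                                       n = 600), seed = model)
    res <- fit_2sls(d, "X", "Y", "G", correct_first_stage = FALSE)
    lm_p <- summary(lm(Y ~ G, data = as.data.frame(d)))$coefficients[2, 4]
    expect_equal(res$p_value, lm_p, tolerance = 1e-12)
  }
})

test_that("point estimate is identical across modes; only se/p differ", {
  d <- simulate_study1(study1_params(model = 2, beta_xy = 0.4, n = 800), 3)
  rc <- fit_2sls(d, "X", "Y", "G", TRUE)
  ru <- fit_2sls(d, "X", "Y", "G", FALSE)
  expect_identical(rc$estimate, ru$estimate)
  expect_false(rc$se == ru$se)
  expect_equal(rc$df, ru$df)
})

test_that("single-instrument estimate equals the Wald ratio", {
  g <- c(0, 0, 1, 1, 2, 2)
  x <- c(0.1, -0.1, 0.5, 0.6, 1.0, 1.1)
  y <- c(0, 0.2, 1.1, 1.3, 2.0, 2.2)
  d <- data.frame(G = g, X = x, Y = y)
  res <- fit_2sls(d, "X", "Y", "G", FALSE)
  expect_equal(res$estimate, cov(g, y) / cov(g, x), tolerance = 1e-12)
})

test_that("an instrument identical to the exposure reduces to OLS", {
  set.seed(4)
  x <- rnorm(200); y <- 0.7 * x + rnorm(200)
  d <- data.frame(G = x, X = x, Y = y)
  res <- suppressWarnings(fit_2sls(d, "X", "Y", "G", TRUE))
  expect_equal(res$estimate, unname(coef(lm(y ~ x))[2]), tolerance = 1e-10)
})

test_that("corrected standard error matches the IV matrix-algebra oracle", {
  d <- simulate_study1(study1_params(model = 1, beta_xy = 0.5, n = 400), 8)
  res <- fit_2sls(d, "X", "Y", "G", TRUE)
  # hand computation: beta_iv = (Zc'X)^-1 Zc'Y with Zc the projection
  # design; sigma^2 from residuals at the observed exposure
  g <- d$G; x <- d$X; y <- d$Y; n <- length(g)
  xhat <- fitted(lm(x ~ g))
  b <- cov(xhat, y) / var(xhat)
  a <- mean(y) - b * mean(xhat)
  sigma2 <- sum((y - a - b * x)^2) / (n - 2)
  se <- sqrt(sigma2 / sum((xhat - mean(xhat))^2))
  expect_equal(res$se, se, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(b / se), n - 2), tolerance = 1e-10)
})

test_that("first-stage p-values come from the joint stage-1 regression", {
  d <- simulate_study1(study1_params(model = 1, beta_xy = 0.2, n = 500), 12)
  d2 <- as.data.frame(d)
  d2$G2 <- rbinom(nrow(d2), 2, 0.4)
  res <- fit_2sls(d2, "X", "Y", c("G", "G2"), TRUE)
  s1 <- summary(lm(X ~ G + G2, data = d2))$coefficients
  expect_equal(unname(res$first_stage_p), unname(s1[2:3, 4]),
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  d <- data.frame(G = rep(1, 50), X = rnorm(50), Y = rnorm(50))
  expect_error(fit_2sls(d, "X", "Y", "G"), "zero-variance")
  d2 <- data.frame(G = rnorm(50), X = rnorm(50), Y = rnorm(50))
  d2$G2 <- d2$G
  expect_error(fit_2sls(d2, "X", "Y", c("G", "G2")), "collinearity")
})

test_that("allele scores are exact weighted allele sums", {
  geno <- rbind(ind1 = c(0, 1, 2), ind2 = c(2, 0, 1))
  colnames(geno) <- c("s1", "s2", "s3")
  sc <- build_allele_score(geno, target = c(0, 0),
                           weights = c(0.5, -0.2, 1.0))
  expect_equal(unname(sc$score), c(1.8, 2.0))
  expect_true(sc$valid)
})

test_that("selection under the null is empty and flagged, not an error", {
  set.seed(9)
  geno <- matrix(rbinom(100 * 300, 2, 0.3), 300,
                 dimnames = list(NULL, paste0("s", 1:100)))
  target <- rnorm(300)
  sc <- build_allele_score(geno, target, selection_threshold = 5e-6)
  expect_false(sc$valid)
  expect_length(sc$snps, 0)
  expect_equal(sc$score, rep(0, 300))
})

test_that("a strongly associated SNP is always selected and dominates", {
  set.seed(10)
  n <- 2500
  geno <- matrix(rbinom(20 * n, 2, 0.3), n,
                 dimnames = list(NULL, paste0("s", 1:20)))
  target <- 1.0 * geno[, "s7"] + rnorm(n)
  sc <- build_allele_score(geno, target, selection_threshold = 5e-6)
  expect_true("s7" %in% sc$snps)
  if (length(sc$snps) == 1L)
    expect_equal(abs(cor(sc$score, geno[, "s7"])), 1, tolerance = 1e-12)
  # marginal regression machinery agrees with lm on a spot check
  mm <- anchorbn:::marginal_regressions(geno, target)
  ref <- summary(lm(target ~ geno[, 3]))$coefficients
  expect_equal(mm$beta[3], ref[2, 1], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mm$p[3], ref[2, 4], tolerance = 1e-10, ignore_attr = TRUE)
})
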