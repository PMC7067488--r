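test_that("detection proportions use strict thresholds on both scales", {
  expect_equal(estimate_power(rep(0.001, 1000), 0.01, "pvalue")$proportion, 1)
  expect_equal(estimate_power(rep(0.75, 10), 0.7, "probability")$proportion, 1)
  expect_equal(estimate_power(rep(0.75, 10), 0.8, "probability")$proportion, 0)
  expect_equal(estimate_power(rep(0.05, 10), 0.05, "pvalue")$proportion, 0)
  expect_error(estimate_power(numeric(0), 0.05), "empty")
})

test_that("uniform p-values reject at the nominal rate", {
  set.seed(51)
  p <- runif(1000)
  est <- estimate_power(p, 0.05, "pvalue")
  expect_lt(abs(est$proportion - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  expect_equal(est$mc_se,
               sqrt(est$proportion * (1 - est$proportion) / 1000))
})

test_that("ROC curves are monotone with correct endpoints", {
  set.seed(52)
  h1 <- runif(200, 0, 0.2); h0 <- runif(200, 0.3, 1)  # separated
  roc <- roc_curve(h1, h0, "pvalue")
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  # exchangeable sets track the diagonal
  same <- runif(400)
  roc2 <- roc_curve(same[1:200], same[201:400], "pvalue")
  expect_lt(max(abs(roc2$fpr - roc2$tpr)), 4 / sqrt(200))
  expect_lt(abs(roc_auc(roc2) - 0.5), 0.1)
})

test_that("every ROC point equals brute-force counting at its threshold", {
  set.seed(53)
  h1 <- round(runif(50), 2); h0 <- round(runif(50), 2)  # force ties
  roc <- roc_curve(h1, h0, "probability")
  for (i in seq_len(nrow(roc))) {
    t <- roc$threshold[i]
    expect_equal(roc$fpr[i], sum(h0 > t) / 50)
    expect_equal(roc$tpr[i], sum(h1 > t) / 50)
  }
})

test_that("direction-probability summaries are exact order statistics", {
  s <- direction_probability_summary(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(s$median, 0.3)
  all1 <- direction_probability_summary(rep(1, 8))
  expect_equal(unlist(all1[, c("min", "q1", "median", "q3", "max")]),
               rep(1, 5), ignore_attr = TRUE)
  # from replicate averaged networks
  mk <- function(cab, cba) {
    counts <- matrix(0L, 2, 2, dimnames = rep(list(c("A", "B")), 2))
    counts["A", "B"] <- cab; counts["B", "A"] <- cba
    structure(list(nodes = c("A", "B"), B = 10L, counts = counts,
                   redraws = 0L), class = "averaged_network")
  }
  nets <- list(mk(10L, 0L), mk(5L, 5L), mk(0L, 10L))
  s2 <- direction_probability_summary(nets, "A", "B")
  expect_equal(s2$median, c(0.5, 0.5))
  expect_equal(s2$max, c(1, 1))
  expect_equal(s2$min, c(0, 0))
})

test_that("experiments are reproducible end to end", {
  cfg <- experiment_config(study = 1, R = 3, B = 15, seed = 4,
                           methods = c("MRp_G", "St_G", "BN_G"),
                           params = study1_params(model = 1, beta_xy = 0.5,
                                                  n = 300))
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$raw, r2$raw)
  expect_identical(r1$summary, r2$summary)
  expect_true(all(r1$summary$proportion >= 0 & r1$summary$proportion <= 1))
  expect_setequal(unique(r1$summary$method), c("MRp_G", "St_G", "BN_G"))
})

test_that("two anchors detect the effect at least as often as one", {
  cfg <- experiment_config(study = 1, R = 30, B = 50, seed = 8,
                           methods = c("BN_GZ", "BN_G"),
                           params = study1_params(model = 1, beta_xy = 0.5,
                                                  n = 2500))
  res <- run_experiment(cfg)
  s <- res$summary
  pow <- function(m) s$proportion[s$method == m & s$direction == "xy" &
                                    s$threshold == 0.8]
  mc <- sqrt(0.25 / 30)
  expect_gte(pow("BN_GZ"), pow("BN_G") - 2 * mc)
})

test_that("the pleiotropic-design harness runs, detects, and reproduces", {
  cfg3 <- study3_config(n = 600, n_snps_total = 120, n_metabolite_snps = 30,
                        n_outcome_snps = 15, n_metabolites = 3,
                        selection_p_threshold = 1e-4)
  cfg <- experiment_config(study = 3, R = 2, B = 25, seed = 10,
                           methods = c("MR", "B1"),
                           params = list(config = cfg3, sparsity = 0.3))
  res <- run_experiment(cfg)
  expect_identical(res$raw, run_experiment(cfg)$raw)
  expect_equal(unname(res$truth),
               c("null", "causal", "reverse"))
  causal <- names(res$truth)[res$truth == "causal"]
  # the causal metabolite is detected forward by MR in these replicates
  expect_true(all(res$raw[, paste0(causal, ".MR.p.xy")] < 0.05))
})
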