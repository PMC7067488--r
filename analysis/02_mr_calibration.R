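#!/usr/bin/env Rscript
# Power and type-I error of the MR engines on the quantitative-trait
# models. MR' (two-stage least squares without first-stage uncertainty
# correction) should be calibrated at the nominal alpha under models 1-2
# and break down under genetic confounding (model 3); MR Steiger trades
# power for protection against using the wrong instrument. Scaled to
# R = 400 replicates per cell (full-scale runs use 1000).

suppressPackageStartupMessages(library(anchorbn))
dir.create("results", showWarnings = FALSE)

R <- 400
rows <- list()
for (model in 1:3) for (beta in c(0, 0.5)) {
  p_mr <- p_mrp <- p_st <- numeric(R)
  for (r in 1:R) {
    d <- simulate_study1(study1_params(model = model, beta_xy = beta),
                         seed = model * 100000 + beta * 10 + r)
    p_mr[r] <- fit_2sls(d, "X", "Y", "G", TRUE)$p_value
    p_mrp[r] <- fit_2sls(d, "X", "Y", "G", FALSE)$p_value
    p_st[r] <- mr_steiger(d, "G", "X", "Y", threshold = 0.05,
                          correct_first_stage = FALSE)$p_value
  }
  for (alpha in c(0.01, 0.05, 0.1)) {
    for (m in c("MR", "MRp", "St")) {
      pv <- switch(m, MR = p_mr, MRp = p_mrp, St = p_st)
      est <- estimate_power(pv, alpha, "pvalue")
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, beta_xy = beta, method = m, alpha = alpha,
        proportion = est$proportion, mc_se = est$mc_se)
    }
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/mr_power_type1.csv", row.names = FALSE)

null5 <- subset(tab, beta_xy == 0 & alpha == 0.05)
cat("type-I error at alpha = 0.05 (beta_XY = 0, R =", R, "):\n")
print(null5[, c("model", "method", "proportion", "mc_se")], row.names = FALSE)
cat("\nmodel 3 shows the genetic-confounding inflation for MR/MR';",
    "MR Steiger pays for its gate with reduced power (see beta_XY = 0.5 rows",
    "in results/mr_power_type1.csv).\n")
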