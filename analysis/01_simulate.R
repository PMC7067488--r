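#!/usr/bin/env Rscript
# Draw one example data set from each simulation family and write them,
# with their variable metadata, under results/datasets/. These are the
# inputs every later stage consumes (the later stages re-simulate at
# scale; the files here document the formats and let the pipeline be
# inspected by hand).

suppressPackageStartupMessages(library(anchorbn))
dir.create("results/datasets", recursive = TRUE, showWarnings = FALSE)

# quantitative traits: no / non-genetic / genetic confounding (written
# at n = 250 to keep the example files small; analyses re-simulate at
# the full n = 2500)
for (model in 1:3) {
  d <- simulate_study1(study1_params(model = model, beta_xy = 0.5, n = 250),
                       seed = model)
  write_dataset(d, sprintf("results/datasets/study1_model%d.csv", model))
}
cat("study 1: models 1-3, written at n = 250 (analysis scale is 2500)\n")

# binary traits: scenarios A-D
for (sc in c("A", "B", "C", "D")) {
  d <- simulate_study2(study2_scenario(sc, n = 500), seed = match(sc, LETTERS))
  write_dataset(d, sprintf("results/datasets/study2_scenario%s.csv", sc))
}
cat("study 2: scenarios A-D, written at n = 500 (analysis scale is 5000)\n")

# pleiotropic design, scaled down for a desk-sized file: the 150+75+null
# SNP structure is kept proportionally at 120 SNPs
cfg <- study3_config(n = 150, n_snps_total = 120, n_metabolite_snps = 30,
                     n_outcome_snps = 15, n_metabolites = 6)
eff <- generate_snp_effects(cfg, seed = 11)
sim <- simulate_study3(cfg, eff, seed = 12)
write_dataset(sim$data, "results/datasets/study3_scaled.csv")
writeLines(paste(names(sim$truth), sim$truth, sep = ","),
           "results/datasets/study3_scaled_truth.csv")
cat("study 3: scaled design, n = 150, 120 SNPs, 6 metabolites; roles:",
    paste(sprintf("%s=%s", names(sim$truth), sim$truth), collapse = " "), "\n")
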