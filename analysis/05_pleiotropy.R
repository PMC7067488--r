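#!/usr/bin/env Rscript
# The pleiotropic design: per-replicate allele scores instrument each
# metabolite and the outcome; MR tests both directions, and the B1
# network (metabolite, Y, and both score nodes with single-outgoing
# constraints) estimates directed edge probabilities. Desk scale: the
# SNP panel is reduced to 600 (structure preserved), R = 40, B = 60;
# the full design uses 10,000 SNPs and 1000 of each.

suppressPackageStartupMessages(library(anchorbn))
dir.create("results", showWarnings = FALSE)

cfg3 <- study3_config(n = 1000, n_snps_total = 600, n_metabolite_snps = 150,
                      n_outcome_snps = 75, n_metabolites = 6)
cfg <- experiment_config(study = 3, R = 40, B = 60, seed = 77,
                         methods = c("MR", "B1"),
                         params = list(config = cfg3, sparsity = 0.15))
res <- run_experiment(cfg)
write.csv(res$summary, "results/pleiotropy_detection.csv", row.names = FALSE)

s <- res$summary
s$truth <- res$truth[sub("\\..*$", "", s$method)]
s$engine <- sub("^[^.]+\\.", "", s$method)
agg <- aggregate(proportion ~ truth + engine + direction + threshold, s, mean)
agg <- agg[agg$threshold %in% c(0.05, 0.8), ]
agg <- agg[order(agg$engine, agg$direction, agg$truth), ]

cat("mean detection proportion by metabolite role (R = 40):\n")
print(agg, row.names = FALSE)
cat("\nreading: MR.xy on 'causal' rows is power; MR.xy on 'reverse' rows is",
    "the inflated type-I error from using a score built on a",
    "Y-driven metabolite; B1 keeps the reverse-direction error low while",
    "retaining forward power.\nper-method table in",
    "results/pleiotropy_detection.csv\n")
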