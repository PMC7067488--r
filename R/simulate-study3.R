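#' Configuration for the pleiotropic SNP-metabolite-outcome design
#'
#' A complex-network design with `n_snps_total` independent SNPs (HWE, MAF
#' uniform on `maf_range`), `n_metabolites` metabolites and one outcome Y:
#' `n_metabolite_snps` SNPs carry effects on the metabolites (a synthetic
#' stand-in for external GWAS beta-coefficients), `n_outcome_snps` distinct
#' SNPs affect Y directly, and the remaining SNPs are null. One third of
#' the metabolites are null, one third causal on Y (coefficient
#' `causal_beta` each) and one third affected by Y in reverse (coefficient
#' `causal_beta`); every structural equation has residual SD `residual_sd`.
#' Allele-score instruments are built per replicate from SNPs passing
#' `selection_p_threshold`.
#'
#' The full-scale defaults are n = 1000 individuals, 10,000 SNPs
#' (150 metabolite + 75 outcome + 9775 null) and 12 metabolites; smaller
#' values scale the design down while preserving its structure.
#'
#' @param n individuals.
#' @param n_snps_total,n_metabolite_snps,n_outcome_snps SNP counts; null
#'   SNPs are the remainder.
#' @param n_metabolites number of metabolites, a multiple of 3 (equal
#'   thirds: null / causal / reverse).
#' @param causal_beta metabolite-outcome effect size.
#' @param residual_sd residual standard deviation of every equation.
#' @param maf_range minor-allele-frequency range, uniform law.
#' @param selection_p_threshold marginal p-value threshold for allele-score
#'   SNP selection.
#' @return a `study3_config` list (with computed `n_null_snps`).
#' @export
study3_config <- function(n = 1000, n_snps_total = 10000,
                          n_metabolite_snps = 150, n_outcome_snps = 75,
                          n_metabolites = 12, causal_beta = 0.3,
                          residual_sd = 1, maf_range = c(0.01, 0.5),
                          selection_p_threshold = 5e-6) {
  n_null <- n_snps_total - n_metabolite_snps - n_outcome_snps
  if (n_null < 0) stop("SNP counts exceed n_snps_total")
  if (n_metabolites %% 3 != 0)
    stop("n_metabolites must split into equal null/causal/reverse thirds")
  if (n <= 0) stop("n must be positive")
  structure(list(n = as.integer(n), n_snps_total = as.integer(n_snps_total),
                 n_metabolite_snps = as.integer(n_metabolite_snps),
                 n_outcome_snps = as.integer(n_outcome_snps),
                 n_null_snps = as.integer(n_null),
                 n_metabolites = as.integer(n_metabolites),
                 causal_beta = causal_beta, residual_sd = residual_sd,
                 maf_range = maf_range,
                 selection_p_threshold = selection_p_threshold),
            class = "study3_config")
}

#' Synthetic SNP effect table for the pleiotropic design
#'
#' Generates a sparse matrix of per-allele SNP-metabolite effects standing
#' in for externally estimated GWAS coefficients, plus the coefficient
#' vector of the outcome SNPs. Every SNP is given one "primary" metabolite
#' (assigned cyclically, so every metabolite has at least one SNP) and
#' additionally affects each other metabolite with probability `sparsity`,
#' emulating widespread pleiotropy among lipid-associated variants.
#' Nonzero per-allele effects have magnitude `|N(effect_mean, effect_sd)|`
#' divided by the allele standard deviation `sqrt(2 maf (1-maf))` (so each
#' carries roughly `effect_mean` standard-deviation units of signal,
#' comfortably detectable at p < 5e-6 for n = 1000) and a random sign.
#' MAFs for the metabolite and outcome SNPs are drawn here and stored, so
#' the table is self-contained, as a real GWAS table with allele
#' frequencies would be.
#'
#' @param config a [study3_config()].
#' @param seed integer seed; identical seeds give identical tables.
#' @param sparsity probability that a SNP affects each non-primary
#'   metabolite; `1` makes the matrix dense.
#' @param effect_mean,effect_sd law of the standardized effect magnitudes.
#' @return a `snp_effects` list with `beta` (metabolite-SNPs x metabolites),
#'   `outcome_beta`, `maf_met`, `maf_out`, and id vectors.
#' @export
generate_snp_effects <- function(config, seed, sparsity = 0.1,
                                 effect_mean = 0.3, effect_sd = 0.1) {
  stopifnot(inherits(config, "study3_config"))
  set.seed(as.integer(seed))
  nm <- config$n_metabolite_snps
  nk <- config$n_metabolites
  maf_met <- stats::runif(nm, config$maf_range[1], config$maf_range[2])
  maf_out <- stats::runif(config$n_outcome_snps,
                          config$maf_range[1], config$maf_range[2])
  sd_g <- sqrt(2 * maf_met * (1 - maf_met))
  nonzero <- matrix(stats::runif(nm * nk) < sparsity, nm, nk)
  nonzero[cbind(seq_len(nm), (seq_len(nm) - 1L) %% nk + 1L)] <- TRUE
  mag <- matrix(abs(stats::rnorm(nm * nk, effect_mean, effect_sd)), nm, nk)
  sgn <- matrix(sample(c(-1, 1), nm * nk, replace = TRUE), nm, nk)
  beta <- ifelse(nonzero, sgn * mag, 0) / sd_g
  sd_go <- sqrt(2 * maf_out * (1 - maf_out))
  outcome_beta <- sample(c(-1, 1), config$n_outcome_snps, replace = TRUE) *
    abs(stats::rnorm(config$n_outcome_snps, effect_mean, effect_sd)) / sd_go
  met_ids <- sprintf("M%02d", seq_len(nk))
  dimnames(beta) <- list(sprintf("snpM%04d", seq_len(nm)), met_ids)
  structure(list(beta = beta, outcome_beta = outcome_beta,
                 maf_met = maf_met, maf_out = maf_out,
                 snp_ids = rownames(beta),
                 outcome_snp_ids = sprintf("snpY%04d",
                                           seq_len(config$n_outcome_snps)),
                 metabolite_ids = met_ids),
            class = "snp_effects")
}

#' Simulate the pleiotropic SNP-metabolite-outcome data set
#'
#' Generates genotypes for all SNPs (HWE binomial draws at the per-SNP
#' MAFs; null-SNP MAFs uniform on the configured range), then, in
#' structural order: causal metabolites from their SNPs; Y from the causal
#' metabolites (coefficient `causal_beta` each) plus the outcome SNPs;
#' reverse metabolites from their SNPs plus Y (coefficient `causal_beta`);
#' null metabolites from their SNPs only. All residual SDs equal
#' `residual_sd`.
#'
#' @param config a [study3_config()].
#' @param effects a [generate_snp_effects()] table conformable with
#'   `config`.
#' @param seed integer seed.
#' @return list with `data` (an [as_dataset()] of all SNPs, metabolites and
#'   Y) and `truth`, the ground-truth role of each metabolite
#'   (`"null"`, `"causal"` or `"reverse"`).
#' @export
simulate_study3 <- function(config, effects, seed) {
  stopifnot(inherits(config, "study3_config"), inherits(effects, "snp_effects"))
  if (nrow(effects$beta) != config$n_metabolite_snps ||
      ncol(effects$beta) != config$n_metabolites ||
      length(effects$outcome_beta) != config$n_outcome_snps)
    stop("effect table does not conform with the configuration")
  set.seed(as.integer(seed))
  n <- config$n
  sd <- config$residual_sd
  nk <- config$n_metabolites
  third <- nk %/% 3L
  truth <- stats::setNames(rep(c("null", "causal", "reverse"), each = third),
                           effects$metabolite_ids)

  draw_geno <- function(maf) {
    m <- length(maf)
    matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  }
  g_met <- draw_geno(effects$maf_met)
  g_out <- draw_geno(effects$maf_out)
  maf_null <- stats::runif(config$n_null_snps,
                           config$maf_range[1], config$maf_range[2])
  g_null <- draw_geno(maf_null)

  genetic <- g_met %*% effects$beta          # n x n_metabolites
  met <- matrix(0, n, nk, dimnames = list(NULL, effects$metabolite_ids))
  causal_ids <- names(truth)[truth == "causal"]
  for (m in causal_ids)
    met[, m] <- genetic[, m] + stats::rnorm(n, 0, sd)
  y <- config$causal_beta * rowSums(met[, causal_ids, drop = FALSE]) +
    drop(g_out %*% effects$outcome_beta) + stats::rnorm(n, 0, sd)
  for (m in names(truth)[truth == "reverse"])
    met[, m] <- genetic[, m] + config$causal_beta * y + stats::rnorm(n, 0, sd)
  for (m in names(truth)[truth == "null"])
    met[, m] <- genetic[, m] + stats::rnorm(n, 0, sd)

  geno <- cbind(g_met, g_out, g_null)
  colnames(geno) <- c(effects$snp_ids, effects$outcome_snp_ids,
                      sprintf("snpN%04d", seq_len(config$n_null_snps)))
  values <- data.frame(geno, met, Y = y, check.names = FALSE)
  role <- c(stats::setNames(rep("instrument", ncol(geno)), colnames(geno)),
            stats::setNames(rep("phenotype", nk), effects$metabolite_ids),
            Y = "outcome")
  list(data = as_dataset(values, kind = "continuous", role = role),
       truth = truth)
}
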