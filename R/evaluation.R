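#' Detection proportion (power or type-I error) over replicates
#'
#' Counts detections among replicate-level p-values (`value < threshold`)
#' or posterior edge probabilities (`value > threshold`); strict
#' inequalities are used in both modes. The Monte Carlo standard error is
#' `sqrt(p (1 - p) / R)`.
#'
#' @param values numeric vector of per-replicate p-values or edge
#'   probabilities, all in \[0, 1\].
#' @param threshold detection threshold.
#' @param mode `"pvalue"` (detect below) or `"probability"` (detect
#'   above).
#' @return list with `proportion`, `mc_se` and `R`.
#' @export
estimate_power <- function(values, threshold,
                           mode = c("pvalue", "probability")) {
  mode <- match.arg(mode)
  if (length(values) == 0L) stop("empty input")
  stopifnot(all(values >= 0 & values <= 1))
  det <- if (mode == "pvalue") values < threshold else values > threshold
  p <- mean(det)
  list(proportion = p, mc_se = sqrt(p * (1 - p) / length(values)),
       R = length(values))
}

#' ROC curve from replicate-level values under alternative and null
#'
#' Sweeps the detection threshold over the pooled value grid: each point
#' has x = false-positive proportion among the null-set values and
#' y = true-positive proportion among the alternative-set values. The
#' null set may come from a no-effect model or from a model with the
#' effect in the wrong direction. Endpoints (0, 0) (strictest) and
#' (1, 1) (loosest) are always included and the curve is monotone
#' non-decreasing in both coordinates.
#'
#' @param h1_values values simulated under the alternative (true effect).
#' @param h0_values values simulated under the null.
#' @inheritParams estimate_power
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, ordered
#'   from strictest to loosest.
#' @export
roc_curve <- function(h1_values, h0_values,
                      mode = c("pvalue", "probability")) {
  mode <- match.arg(mode)
  if (length(h1_values) == 0L || length(h0_values) == 0L)
    stop("empty input")
  pooled <- sort(unique(c(h1_values, h0_values)))
  if (mode == "pvalue") {
    thresholds <- c(0, pooled, Inf)
    detect <- function(v, t) v < t
  } else {
    thresholds <- c(Inf, rev(pooled), -Inf)
    detect <- function(v, t) v > t
  }
  fpr <- vapply(thresholds, function(t) mean(detect(h0_values, t)), numeric(1))
  tpr <- vapply(thresholds, function(t) mean(detect(h1_values, t)), numeric(1))
  data.frame(threshold = thresholds, fpr = fpr, tpr = tpr)
}

#' Area under an ROC curve by the trapezoidal rule
#'
#' @param roc a data.frame from [roc_curve()].
#' @return scalar AUC.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Distribution of direction probabilities across replicates
#'
#' Five-number summary (minimum, lower hinge, median, upper hinge,
#' maximum - the box-plot statistics) of the bootstrap probability that a
#' directed edge exists, across replicate averaged networks, for both
#' orientations of a pair.
#'
#' @param nets list of `averaged_network` objects (one per replicate), or
#'   a numeric vector of per-replicate probabilities for the forward
#'   direction only.
#' @param a,b node names (ignored when `nets` is numeric).
#' @return data.frame with one row per orientation and columns `min`,
#'   `q1`, `median`, `q3`, `max`.
#' @export
direction_probability_summary <- function(nets, a = NULL, b = NULL) {
  if (is.numeric(nets)) {
    fw <- nets
    fn <- stats::fivenum(fw)
    return(data.frame(direction = "forward", min = fn[1], q1 = fn[2],
                      median = fn[3], q3 = fn[4], max = fn[5]))
  }
  stopifnot(length(nets) >= 1L, !is.null(a), !is.null(b))
  fw <- vapply(nets, edge_probability, numeric(1), a = a, b = b)
  bw <- vapply(nets, edge_probability, numeric(1), a = b, b = a)
  out <- rbind(stats::fivenum(fw), stats::fivenum(bw))
  data.frame(direction = c("forward", "backward"),
             min = out[, 1], q1 = out[, 2], median = out[, 3],
             q3 = out[, 4], max = out[, 5])
}

#' Experiment configuration for the replicate-level harness
#'
#' Bundles the generating model, the methods to run, the replicate count
#' and the detection-threshold grids. The full-scale design uses R = 1000
#' replicates and B = 1000 bootstrap networks; both can be scaled down
#' for desk-sized runs while preserving the structure of the experiment.
#'
#' @param study 1 (quantitative traits) or 3 (pleiotropic design).
#' @param R replicates.
#' @param B bootstrap networks per replicate (BN methods).
#' @param seed base seed; replicate r uses `seed + r`.
#' @param methods methods to run. Study 1: subsets of
#'   `c("MR_G", "MRp_G", "MR_Z", "MRp_Z", "St_G", "St_Z", "BN_GZ",
#'   "BN_G", "BN_Z")` (MRp = two-stage least squares without first-stage
#'   uncertainty correction; suffix names the instrument(s) / anchors).
#'   Study 3: subsets of `c("MR", "B1")`.
#' @param params generating parameters: a [study1_params()] for study 1;
#'   for study 3 a list with elements `config` (a [study3_config()]) and
#'   optionally `effects_seed`, `sparsity`.
#' @param alpha_grid p-value detection thresholds.
#' @param prob_grid posterior-probability detection thresholds.
#' @param restarts hill-climbing restarts for BN methods.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(study = 1, R = 1000, B = 1000, seed = 1,
                              methods = NULL, params = NULL,
                              alpha_grid = c(0.01, 0.05, 0.1),
                              prob_grid = c(0.7, 0.8, 0.9),
                              restarts = 0) {
  stopifnot(study %in% c(1, 3), R >= 1,
            all(alpha_grid > 0 & alpha_grid < 1),
            all(prob_grid > 0 & prob_grid < 1))
  if (is.null(methods))
    methods <- if (study == 1) c("MR_G", "MRp_G", "MR_Z", "MRp_Z",
                                 "St_G", "St_Z", "BN_GZ", "BN_G", "BN_Z")
               else c("MR", "B1")
  if (is.null(params))
    params <- if (study == 1) study1_params() else list(config = study3_config())
  structure(list(study = study, R = as.integer(R), B = as.integer(B),
                 seed = as.integer(seed), methods = methods, params = params,
                 alpha_grid = alpha_grid, prob_grid = prob_grid,
                 restarts = restarts),
            class = "experiment_config")
}

#' Run a replicate-level simulation experiment
#'
#' For each replicate: simulate a data set under the configured model,
#' run every configured method, and record its replicate-level evidence
#' (an MR p-value, or a bootstrap edge probability for each direction).
#' Results are aggregated into detection proportions at each threshold
#' of the configured grids. Fully reproducible: replicate r derives all
#' its randomness from `seed + r`, and a method failure inside a
#' replicate is recorded as a non-detection rather than aborting the run.
#'
#' @param config an [experiment_config()].
#' @return list with `raw` (per-replicate value matrix, one column per
#'   recorded quantity), `summary` (long data.frame: method, direction,
#'   threshold, proportion, mc_se) and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- vector("list", config$R)
  for (r in seq_len(config$R)) {
    rows[[r]] <- if (config$study == 1) study1_replicate(config, r)
                 else study3_replicate(config, r)
  }
  truth <- attr(rows[[1]], "truth")
  raw <- do.call(rbind, rows)
  summary <- summarize_replicates(raw, config)
  list(raw = raw, summary = summary, config = config, truth = truth)
}

# one study-1 replicate: returns a named numeric vector of p-values /
# edge probabilities; failures inside a method yield a non-detection
study1_replicate <- function(config, r) {
  data <- simulate_study1(config$params, seed = config$seed + r)
  vars <- c("G", "Z", "X", "Y")
  out <- c()
  safe_p <- function(expr) tryCatch(expr, error = function(e) 1)
  for (m in config$methods) {
    val <- switch(m,
      MR_G = c(p.xy = safe_p(fit_2sls(data, "X", "Y", "G", TRUE)$p_value)),
      MRp_G = c(p.xy = safe_p(fit_2sls(data, "X", "Y", "G", FALSE)$p_value)),
      MR_Z = c(p.yx = safe_p(fit_2sls(data, "Y", "X", "Z", TRUE)$p_value)),
      MRp_Z = c(p.yx = safe_p(fit_2sls(data, "Y", "X", "Z", FALSE)$p_value)),
      St_G = c(p.xy = safe_p(mr_steiger(data, "G", "X", "Y",
                                        threshold = 0.05)$p_value),
               p.yx = safe_p(mr_steiger(data, "G", "Y", "X",
                                        threshold = 0.05)$p_value)),
      St_Z = c(p.xy = safe_p(mr_steiger(data, "Z", "X", "Y",
                                        threshold = 0.05)$p_value),
               p.yx = safe_p(mr_steiger(data, "Z", "Y", "X",
                                        threshold = 0.05)$p_value)),
      BN_GZ = bn_direction_probs(data[, vars], c("G", "Z"), config, r),
      BN_G = bn_direction_probs(data[, c("G", "X", "Y")], "G", config, r),
      BN_Z = bn_direction_probs(data[, c("Z", "X", "Y")], "Z", config, r),
      stop("unknown study-1 method: ", m))
    names(val) <- paste0(m, ".", names(val))
    out <- c(out, val)
  }
  out
}

bn_direction_probs <- function(data, anchors, config, r) {
  cs <- no_incoming(constraint_set(names(data)), anchors)
  net <- bootstrap_average(data, cs, B = config$B,
                           seed = (config$seed + r) * 1000L,
                           restarts = config$restarts)
  c(prob.xy = edge_probability(net, "X", "Y"),
    prob.yx = edge_probability(net, "Y", "X"))
}

# one study-3 replicate: per metabolite, MR in both directions using
# freshly built allele scores, and the B1 four-node network
study3_replicate <- function(config, r) {
  p3 <- config$params
  cfg <- p3$config
  effects <- generate_snp_effects(cfg, seed = p3$effects_seed %||% config$seed,
                                  sparsity = p3$sparsity %||% 0.1)
  sim <- simulate_study3(cfg, effects, seed = config$seed + r)
  data <- sim$data
  snp_cols <- names(data)[startsWith(names(data), "snp")]
  geno <- as.matrix(as.data.frame(data)[, snp_cols])
  score_y <- build_allele_score(geno, data[["Y"]],
                                selection_threshold = cfg$selection_p_threshold)
  out <- c()
  for (m in effects$metabolite_ids) {
    score_m <- build_allele_score(geno, data[[m]],
                                  selection_threshold = cfg$selection_p_threshold)
    vals <- c()
    if ("MR" %in% config$methods) {
      vals <- c(vals,
        MR.p.xy = mr_score_p(data[[m]], data[["Y"]], score_m),
        MR.p.yx = mr_score_p(data[["Y"]], data[[m]], score_y))
    }
    if ("B1" %in% config$methods) {
      bp <- b1_probs(data[[m]], data[["Y"]], score_m, score_y, config, r)
      names(bp) <- paste0("B1.", names(bp))
      vals <- c(vals, bp)
    }
    names(vals) <- paste0(m, ".", names(vals))
    out <- c(out, vals)
  }
  attr(out, "truth") <- sim$truth
  out
}

mr_score_p <- function(exposure, outcome, score) {
  if (!score$valid) return(1)
  df <- data.frame(S = score$score, E = exposure, O = outcome)
  tryCatch(fit_2sls(df, "E", "O", "S", TRUE)$p_value, error = function(e) 1)
}

b1_probs <- function(met, y, score_m, score_y, config, r) {
  vals <- data.frame(M = met, Y = y)
  scores <- character(0)
  if (score_m$valid) { vals$SM <- score_m$score; scores <- c(scores, "SM") }
  if (score_y$valid) { vals$SY <- score_y$score; scores <- c(scores, "SY") }
  cs <- constraint_set(names(vals))
  if ("SM" %in% scores) cs <- single_outgoing(cs, "SM", "M")
  if ("SY" %in% scores) cs <- single_outgoing(cs, "SY", "Y")
  net <- bootstrap_average(as_dataset(vals), cs, B = config$B,
                           seed = (config$seed + r) * 1000L,
                           restarts = config$restarts)
  c(prob.xy = edge_probability(net, "M", "Y"),
    prob.yx = edge_probability(net, "Y", "M"))
}

summarize_replicates <- function(raw, config) {
  cols <- colnames(raw)
  out <- list()
  for (cn in cols) {
    parts <- strsplit(cn, ".", fixed = TRUE)[[1]]
    kind <- parts[length(parts) - 1L]
    direction <- parts[length(parts)]
    method <- paste(parts[-c(length(parts) - 1L, length(parts))],
                    collapse = ".")
    grid <- if (kind == "p") config$alpha_grid else config$prob_grid
    mode <- if (kind == "p") "pvalue" else "probability"
    for (th in grid) {
      est <- estimate_power(raw[, cn], th, mode)
      out[[length(out) + 1L]] <- data.frame(
        method = method, direction = direction, mode = mode, threshold = th,
        proportion = est$proportion, mc_se = est$mc_se,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
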