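#' Steiger directionality test for an instrument shared by two traits
#'
#' Decides whether a genetic variable is better suited as an instrument for
#' `trait_a` or `trait_b` by comparing the two dependent correlations
#' r(instrument, a) and r(instrument, b), which share the instrument and
#' are correlated through r(a, b). Because allele coding makes the sign
#' of an instrument-trait correlation arbitrary, the comparison is made
#' on correlation magnitudes (equivalently, explained variance). The
#' test statistic is Steiger's (1980) Z-bar for correlated correlations
#' with one variable in common, applied to `|r|`: with Fisher transforms
#' `z1 = atanh(r_ga)`, `z2 = atanh(r_gb)`,
#' `rm2 = (r_ga^2 + r_gb^2)/2`, `f = min((1 - r_ab) / (2 (1 - rm2)), 1)`
#' and `h = (1 - f * rm2) / (1 - rm2)`,
#'
#'   `Z = (z1 - z2) * sqrt((n - 3) / (2 (1 - r_ab) h))`
#'
#' with a two-sided normal p-value. The preferred exposure is the trait
#' with the larger absolute correlation with the instrument. The
#' instrument is declared valid for `trait_a` (the requested exposure)
#' when its first-stage association p-value and the Steiger p-value both
#' fall below `threshold` and the preferred exposure is `trait_a`.
#'
#' @param data an [as_dataset()] or data.frame.
#' @param instrument,trait_a,trait_b column names; `trait_a` is the
#'   requested exposure.
#' @param threshold p-value threshold for both gates (default 0.05).
#' @return a `steiger_result` list: `r_gx`, `r_gy`, `r_xy`, `z_stat`,
#'   `p_value`, `preferred_exposure`, `instrument_valid`, `first_stage_p`.
#' @export
steiger_direction_test <- function(data, instrument, trait_a, trait_b,
                                   threshold = 0.05) {
  stopifnot(all(c(instrument, trait_a, trait_b) %in% names(data)))
  g <- data[[instrument]]; a <- data[[trait_a]]; b <- data[[trait_b]]
  if (stats::sd(g) == 0 || stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant column")
  n <- length(g)
  r_ga <- stats::cor(g, a)
  r_gb <- stats::cor(g, b)
  r_ab <- stats::cor(a, b)
  # the sign of an instrument-trait correlation is arbitrary (allele
  # coding); suitability is about explained variance, so the test
  # compares correlation magnitudes
  z <- steiger_z(abs(r_ga), abs(r_gb), abs(r_ab), n)
  p <- 2 * stats::pnorm(-abs(z))
  preferred <- if (abs(r_ga) >= abs(r_gb)) trait_a else trait_b
  fs <- stats::cor.test(g, a)$p.value
  valid <- (fs < threshold) && (p < threshold) && identical(preferred, trait_a)
  structure(list(r_gx = r_ga, r_gy = r_gb, r_xy = r_ab,
                 z_stat = z, p_value = p,
                 preferred_exposure = preferred,
                 instrument_valid = valid, first_stage_p = fs,
                 threshold = threshold),
            class = "steiger_result")
}

steiger_z <- function(r_ga, r_gb, r_ab, n) {
  if (r_ga == r_gb) return(0)
  z1 <- atanh(r_ga); z2 <- atanh(r_gb)
  rm2 <- (r_ga^2 + r_gb^2) / 2
  f <- min((1 - r_ab) / (2 * (1 - rm2)), 1)
  h <- (1 - f * rm2) / (1 - rm2)
  (z1 - z2) * sqrt((n - 3) / (2 * (1 - r_ab) * h))
}

#' MR Steiger: direction-gated Mendelian randomization
#'
#' Runs [steiger_direction_test()] for `instrument` against the requested
#' `exposure` and the `outcome`; when the instrument is declared valid for
#' the exposure, a standard [fit_2sls()] MR test of exposure on outcome is
#' performed with that instrument. When the gate fails (the instrument is
#' too weak, the direction test is inconclusive, or the instrument is more
#' strongly correlated with the outcome), a flagged non-detection is
#' returned with a sentinel p-value of 1 rather than an error, so
#' replicate loops stay alive.
#'
#' @inheritParams fit_2sls
#' @param instrument single candidate instrument column name.
#' @param threshold p-value threshold used by both Steiger gates (defaults
#'   to the final MR alpha in typical use).
#' @return an `mr_result` with an added `steiger` field; `detected` is
#'   `FALSE` and `p_value` 1 when the instrument is invalid.
#' @export
mr_steiger <- function(data, instrument, exposure, outcome, threshold = 0.05,
                       correct_first_stage = TRUE) {
  st <- steiger_direction_test(data, instrument, exposure, outcome, threshold)
  if (!st$instrument_valid) {
    res <- structure(list(estimate = NA_real_, se = NA_real_, p_value = 1,
                          df = length(data[[exposure]]) - 2L,
                          instruments = instrument,
                          first_stage_p = stats::setNames(st$first_stage_p,
                                                          instrument),
                          mode = if (correct_first_stage) "corrected"
                                 else "uncorrected",
                          exposure = exposure, outcome = outcome,
                          detected = FALSE),
                     class = "mr_result")
    res$steiger <- st
    return(res)
  }
  res <- fit_2sls(data, exposure, outcome, instrument,
                  correct_first_stage = correct_first_stage)
  res$steiger <- st
  res$detected <- res$p_value < threshold
  res
}
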