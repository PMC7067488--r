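#' Parameters for the quantitative-trait simulation models
#'
#' Three structural models over two continuous phenotypes X and Y, a SNP
#' instrument G (coded 0/1/2 under Hardy-Weinberg equilibrium) for X and a
#' continuous instrument Z for Y:
#'
#' * model 1 - no confounding: `G -> X -> Y <- Z`;
#' * model 2 - non-genetic confounding: model 1 plus a latent-style measured
#'   confounder C with `C -> X` and `C -> Y`;
#' * model 3 - genetic confounding (horizontal pleiotropy): model 1 plus a
#'   second phenotype S on the path `G -> S -> Y`, so G affects Y through a
#'   channel other than X.
#'
#' Every structural equation has residual standard deviation
#' `residual_sd` (default 1). The standard presets fix
#' `beta_gx = 0.1`, `beta_zy = 0.075` and set the four confounding
#' coefficients (`beta_cx`, `beta_cy`, `beta_gs`, `beta_sy`) to 0.25
#' ("weak") or 0.5 ("strong"). The causal effect between X and Y is
#' `beta_xy` when `direction = "x_to_y"` and `beta_yx` when
#' `direction = "y_to_x"` (the structural roles of X and Y swap, giving the
#' wrong-direction null used for ROC false-positive rates); exactly one of
#' the two may be nonzero.
#'
#' @param model 1, 2 or 3.
#' @param beta_xy effect of X on Y (active when `direction = "x_to_y"`).
#' @param beta_yx effect of Y on X (active when `direction = "y_to_x"`).
#' @param direction `"x_to_y"` or `"y_to_x"`.
#' @param confounding `"weak"` or `"strong"` preset for the confounding
#'   coefficients.
#' @param n number of individuals (default 2500).
#' @param maf_g allele frequency of G in (0,1); the generating law of G is
#'   Binomial(2, maf) under HWE.
#' @param beta_gx,beta_zy instrument strengths.
#' @param beta_cx,beta_cy,beta_gs,beta_sy confounding coefficients;
#'   defaulted from `confounding` when `NULL`.
#' @param residual_sd residual standard deviation of every structural
#'   equation.
#' @return a `study1_params` list.
#' @export
study1_params <- function(model = 1, beta_xy = 0.5, beta_yx = 0,
                          direction = c("x_to_y", "y_to_x"),
                          confounding = c("weak", "strong"),
                          n = 2500, maf_g = 0.3,
                          beta_gx = 0.1, beta_zy = 0.075,
                          beta_cx = NULL, beta_cy = NULL,
                          beta_gs = NULL, beta_sy = NULL,
                          residual_sd = 1) {
  direction <- match.arg(direction)
  confounding <- match.arg(confounding)
  if (!model %in% 1:3) stop("unknown model id: ", model)
  if (n <= 0) stop("n must be positive")
  if (maf_g <= 0 || maf_g >= 1) stop("maf_g must lie in (0,1)")
  conf <- if (confounding == "weak") 0.25 else 0.5
  p <- list(model = as.integer(model), beta_xy = beta_xy, beta_yx = beta_yx,
            direction = direction, confounding = confounding,
            n = as.integer(n), maf_g = maf_g,
            beta_gx = beta_gx, beta_zy = beta_zy,
            beta_cx = if (is.null(beta_cx)) conf else beta_cx,
            beta_cy = if (is.null(beta_cy)) conf else beta_cy,
            beta_gs = if (is.null(beta_gs)) conf else beta_gs,
            beta_sy = if (is.null(beta_sy)) conf else beta_sy,
            residual_sd = residual_sd)
  if (direction == "x_to_y" && beta_yx != 0)
    stop("beta_yx must be 0 when direction is x_to_y")
  if (direction == "y_to_x" && beta_xy != 0)
    stop("beta_xy must be 0 when direction is y_to_x")
  class(p) <- "study1_params"
  p
}

#' Simulate a quantitative-trait data set
#'
#' Draws one data set from the structural model described in
#' [study1_params()]. Variables are generated in topological order with
#' independent Gaussian residuals of standard deviation `residual_sd`:
#' G ~ Binomial(2, maf)/HWE, Z ~ N(0,1), C ~ N(0,1) (model 2 only),
#' S ~ N(beta_gs G, sd) (model 3 only), then X and Y per the active
#' direction. All columns are declared continuous, matching how the
#' network analyses treat them.
#'
#' @param params a [study1_params()] object.
#' @param seed integer seed; identical `(params, seed)` give identical
#'   data sets.
#' @return an [as_dataset()] with columns G, Z, X, Y and, for models 2 and
#'   3 respectively, C or S.
#' @export
simulate_study1 <- function(params, seed) {
  stopifnot(inherits(params, "study1_params"))
  set.seed(as.integer(seed))
  n <- params$n
  sd <- params$residual_sd
  g <- stats::rbinom(n, 2L, params$maf_g)
  z <- stats::rnorm(n)
  cval <- if (params$model == 2) stats::rnorm(n) else NULL
  sval <- if (params$model == 3) stats::rnorm(n, params$beta_gs * g, sd) else NULL
  mu_x_base <- params$beta_gx * g +
    (if (params$model == 2) params$beta_cx * cval else 0)
  mu_y_base <- params$beta_zy * z +
    (if (params$model == 2) params$beta_cy * cval else 0) +
    (if (params$model == 3) params$beta_sy * sval else 0)
  if (params$direction == "x_to_y") {
    x <- stats::rnorm(n, mu_x_base, sd)
    y <- stats::rnorm(n, params$beta_xy * x + mu_y_base, sd)
  } else {
    y <- stats::rnorm(n, mu_y_base, sd)
    x <- stats::rnorm(n, params$beta_yx * y + mu_x_base, sd)
  }
  values <- data.frame(G = g, Z = z, X = x, Y = y)
  role <- c(G = "instrument", Z = "instrument", X = "phenotype", Y = "outcome")
  if (params$model == 2) {
    values$C <- cval
    role <- c(role, C = "confounder")
  } else if (params$model == 3) {
    values$S <- sval
    role <- c(role, S = "confounder")
  }
  as_dataset(values, kind = "continuous", role = role)
}
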