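#' Parameters for the binary-trait simulation scenarios
#'
#' Four binary variables on the graph `Q -> W`, `Q -> H <- W`,
#' `{Q, W, H} -> Y`: a genetic variant Q, an exposure W (high alcohol), a
#' mediator H (high alanine transaminase) and a disease outcome Y
#' (hepatocellular carcinoma). Q is Bernoulli(`freq_q`); each downstream
#' variable is Bernoulli with success probability
#' `plogis(linear predictor)` using the scenario coefficients, generated in
#' topological order Q, W, H, Y:
#'
#' * `P(W=1) = plogis(delta_0 + delta_q Q)`
#' * `P(H=1) = plogis(alpha_0 + alpha_q Q + alpha_w W)`
#' * `P(Y=1) = plogis(beta_0 + beta_q Q + beta_w W + beta_h H)`
#'
#' The four standard scenarios A-D are available through
#' [study2_scenario()]. Coefficients include negative values, so a logistic
#' link is used throughout (an additive-probability model would be
#' infeasible for these coefficient sets).
#'
#' @param freq_q probability that Q = 1, in (0,1).
#' @param beta_0,beta_q,beta_w,beta_h coefficients of the Y equation.
#' @param alpha_0,alpha_q,alpha_w coefficients of the H equation.
#' @param delta_0,delta_q coefficients of the W equation.
#' @param n number of individuals (default 5000).
#' @return a `scenario_params` list.
#' @export
scenario_params <- function(freq_q, beta_0, beta_q, beta_w, beta_h,
                            alpha_0, alpha_q, alpha_w,
                            delta_0, delta_q, n = 5000) {
  cf <- c(freq_q, beta_0, beta_q, beta_w, beta_h,
          alpha_0, alpha_q, alpha_w, delta_0, delta_q)
  if (!all(is.finite(cf))) stop("all coefficients must be finite")
  if (freq_q <= 0 || freq_q >= 1) stop("freq_q must lie in (0,1)")
  if (n <= 0) stop("n must be positive")
  structure(list(freq_q = freq_q, beta_0 = beta_0, beta_q = beta_q,
                 beta_w = beta_w, beta_h = beta_h, alpha_0 = alpha_0,
                 alpha_q = alpha_q, alpha_w = alpha_w, delta_0 = delta_0,
                 delta_q = delta_q, n = as.integer(n)),
            class = "scenario_params")
}

#' @rdname scenario_params
#' @param scenario one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
study2_scenario <- function(scenario = c("A", "B", "C", "D"), n = 5000) {
  scenario <- match.arg(scenario)
  row <- switch(scenario,
    A = c(0.49,  0.2,  0.3,  0.25, 0.15, 0.2, 0.4, 0.2, 0.1, 0.3),
    B = c(0.49, -0.9, -0.3, -0.1,  0.2,  0.0, 0.2, 0.2, 0.2, 0.3),
    C = c(0.49, -1.0, -1.0, -0.8,  0.2,  0.0, 0.2, 0.2, 0.2, 0.3),
    D = c(0.49,  0.2,  0.2,  0.2,  0.1,  0.1, 0.2, 0.2, 0.1, 0.2))
  scenario_params(row[1], row[2], row[3], row[4], row[5],
                  row[6], row[7], row[8], row[9], row[10], n = n)
}

#' Simulate a binary-trait data set
#'
#' @param params a [scenario_params()] object (see [study2_scenario()] for
#'   the standard presets).
#' @param seed integer seed.
#' @return an [as_dataset()] with categorical 0/1 columns Q, W, H, Y.
#' @export
simulate_study2 <- function(params, seed) {
  stopifnot(inherits(params, "scenario_params"))
  set.seed(as.integer(seed))
  n <- params$n
  q <- stats::rbinom(n, 1L, params$freq_q)
  w <- stats::rbinom(n, 1L, stats::plogis(params$delta_0 + params$delta_q * q))
  h <- stats::rbinom(n, 1L, stats::plogis(params$alpha_0 + params$alpha_q * q +
                                            params$alpha_w * w))
  y <- stats::rbinom(n, 1L, stats::plogis(params$beta_0 + params$beta_q * q +
                                            params$beta_w * w + params$beta_h * h))
  as_dataset(data.frame(Q = q, W = w, H = h, Y = y),
             kind = "categorical",
             role = c(Q = "instrument", W = "phenotype", H = "phenotype",
                      Y = "outcome"),
             levels = list(Q = 0:1, W = 0:1, H = 0:1, Y = 0:1))
}
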