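#' Parameters of the coupled Holling type II growth system
#'
#' Bundles the six parameters of the two-species growth model: each species
#' grows logistically towards its own carrying capacity and is pushed up or
#' down by its partner through a saturating (Holling type II) interaction
#' term,
#' \deqn{dE/dt = r_e E (1 - E/K_e) + r_e E \frac{\alpha_{E \leftarrow S}}{1+E} S,}
#' \deqn{dS/dt = r_s S (1 - S/K_s) + r_s S \frac{\alpha_{S \leftarrow E}}{1+S} E.}
#'
#' @param r_e,r_s Malthusian growth rates (per hour, > 0).
#' @param K_e,K_s Carrying capacities (abundance units, > 0).
#' @param alpha_es Interaction scalar: effect of species S on species E
#'   (positive = benefit, negative = harm, zero = neutral).
#' @param alpha_se Interaction scalar: effect of species E on species S.
#' @return An object of class `hlv_params` (a named list).
#' @export
#' @examples
#' hlv_params(r_e = 0.5, K_e = 24, alpha_es = -0.01,
#'            r_s = 0.4, K_s = 21, alpha_se = -0.02)
hlv_params <- function(r_e, K_e, alpha_es, r_s, K_s, alpha_se) {
  x <- c(r_e = r_e, K_e = K_e, alpha_es = alpha_es,
         r_s = r_s, K_s = K_s, alpha_se = alpha_se)
  if (!all(is.finite(x)))
    stop("all parameters must be finite")
  if (any(x[c("r_e", "K_e", "r_s", "K_s")] <= 0))
    stop("r_e, K_e, r_s, K_s must be strictly positive")
  structure(as.list(x), class = "hlv_params")
}

theta_names <- function() c("r_e", "K_e", "alpha_es", "r_s", "K_s", "alpha_se")

as_theta_vec <- function(params) {
  if (inherits(params, "hlv_params") || is.list(params))
    params <- unlist(params[theta_names()])
  stopifnot(length(params) == 6L)
  unname(params)
}

#' Right-hand side of the coupled growth system
#'
#' Evaluates the derivative pair (dE/dt, dS/dt) at a given state.
#'
#' @param state Numeric vector `c(E, S)`, non-negative abundances.
#' @param params An [hlv_params()] object.
#' @return Named numeric vector `c(dE, dS)`.
#' @export
hlv_rhs <- function(state, params) {
  if (length(state) != 2L || !all(is.finite(state)))
    stop("state must be two finite abundances")
  if (any(state < 0)) stop("state must be non-negative")
  p <- as_theta_vec(params)
  E <- state[[1]]; S <- state[[2]]
  dE <- p[1] * E * (1 - E / p[2]) + p[1] * E * (p[3] / (1 + E)) * S
  dS <- p[4] * S * (1 - S / p[5]) + p[4] * S * (p[6] / (1 + S)) * E
  c(dE = dE, dS = dS)
}

check_times <- function(times) {
  if (length(times) < 1L || !all(is.finite(times)))
    stop("times must be finite")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  as.numeric(times)
}

#' Solve the coupled growth system by fixed-step fourth-order Runge-Kutta
#'
#' Integrates the two-species system from the state at the first requested
#' time, splitting every inter-observation interval into equal sub-steps no
#' longer than `step` so that the integration grid lands exactly on the
#' requested times.
#'
#' @param params An [hlv_params()] object.
#' @param init Numeric `c(E0, S0)`, the state at `times[1]`.
#' @param times Strictly increasing observation times (hours).
#' @param step Maximum integration step (hours); default 0.01.
#' @return A data frame with columns `time`, `E`, `S`.
#' @export
solve_hlv <- function(params, init, times, step = 0.01) {
  times <- check_times(times)
  if (length(init) != 2L || any(!is.finite(init)) || any(init < 0))
    stop("init must be two finite non-negative abundances")
  if (step <= 0) stop("step must be positive")
  m <- cpp_solve_hlv(as_theta_vec(params), init[[1]], init[[2]], times, step)
  data.frame(time = times, E = m[, 1], S = m[, 2])
}

#' Decompose trajectories into independent and interaction-dependent growth
#'
#' The net trajectory of each species is split into an *independent*
#' component -- the standalone logistic solution with the same growth rate,
#' capacity and initial state, i.e. how the species would grow in
#' monoculture -- and a *dependent* component, defined as net minus
#' independent, attributable to the partner species.
#'
#' @inheritParams solve_hlv
#' @return A data frame with columns `time`, `net_E`, `net_S`,
#'   `independent_E`, `independent_S`, `dependent_E`, `dependent_S`.
#'   `net = independent + dependent` holds exactly at every time.
#' @export
decompose_trajectory <- function(params, init, times, step = 0.01) {
  p <- as_theta_vec(params)
  net <- solve_hlv(p, init, times, step)
  p0 <- p; p0[c(3, 6)] <- 0
  ind <- solve_hlv(p0, init, times, step)
  data.frame(time = net$time,
             net_E = net$E, net_S = net$S,
             independent_E = ind$E, independent_S = ind$S,
             dependent_E = net$E - ind$E, dependent_S = net$S - ind$S)
}

#' Classical growth-curve parameter sets
#'
#' @param model One of `"logistic"`, `"gompertz"`, `"richards"`.
#' @param K Asymptote (> 0).
#' @param a Shape parameter.
#' @param b Rate parameter.
#' @param m Richards exponent; required (and only allowed) for
#'   `model = "richards"`.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(model = c("logistic", "gompertz", "richards"),
                          K, a, b, m = NULL) {
  model <- match.arg(model)
  if (!is.finite(K) || K <= 0) stop("K must be positive")
  if (model == "richards") {
    if (is.null(m)) stop("richards model requires m")
    if (m == 0) stop("richards exponent m must be nonzero")
  } else if (!is.null(m)) {
    stop("m is only meaningful for the richards model")
  }
  structure(list(model = model, K = K, a = a, b = b, m = m),
            class = "growth_params")
}

#' Evaluate a classical growth curve
#'
#' Parameterizations: logistic \eqn{K/(1+a e^{-bt})}; Gompertz
#' \eqn{K \exp(-a e^{-bt})}; Richards \eqn{K/(1+a e^{-bt})^{1/m}}.
#'
#' @param params A [growth_params()] object.
#' @param times Numeric vector of times.
#' @return Numeric vector of abundances.
#' @export
classical_growth_curve <- function(params, times) {
  stopifnot(inherits(params, "growth_params"))
  e <- exp(-params$b * times)
  switch(params$model,
         logistic = params$K / (1 + params$a * e),
         gompertz = params$K * exp(-params$a * e),
         richards = params$K / (1 + params$a * e)^(1 / params$m))
}

# Closed-form logistic used as an analytic oracle for the alpha = 0 case.
logistic_closed_form <- function(r, K, x0, t) {
  t0 <- t - t[1]
  K * x0 * exp(r * t0) / (K + x0 * (exp(r * t0) - 1))
}
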