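#' Information criteria from a Gaussian log-likelihood
#'
#' `AIC = 2k - 2l`, `BIC = k log(n) - 2l`, `HQ = 2k log(log(n)) - 2l`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters (>= 0).
#' @param n Number of observations (>= 1; >= 3 for HQ).
#' @return Named vector `c(AIC, BIC, HQ)`.
#' @export
information_criteria <- function(loglik, k, n) {
  if (!is.finite(loglik)) stop("loglik must be finite")
  if (k < 0) stop("k must be non-negative")
  if (n < 1) stop("n must be >= 1")
  if (n < 3) stop("HQ criterion requires n >= 3 (log(log(n)) domain)")
  c(AIC = 2 * k - 2 * loglik,
    BIC = k * log(n) - 2 * loglik,
    HQ = 2 * k * log(log(n)) - 2 * loglik)
}

# R^2 with the convention that constant data (zero total sum of squares)
# has R^2 = 0
r_squared <- function(y, fitted) {
  sst <- sum((y - mean(y))^2)
  ssr <- sum((y - fitted)^2)
  if (sst <= .Machine$double.eps * max(1, sum(y^2))) return(0)
  1 - ssr / sst
}

gaussian_profile_loglik <- function(ssr, n) {
  s2 <- max(ssr / n, .Machine$double.eps)
  -n / 2 * (log(2 * pi * s2) + 1)
}

make_fit_report <- function(model, estimates, se, y, fitted, k, converged) {
  n <- length(y)
  ssr <- sum((y - fitted)^2)
  r2 <- r_squared(y, fitted)
  adj_r2 <- if (n > k + 1) 1 - (1 - r2) * (n - 1) / (n - k - 1) else NA_real_
  ll <- gaussian_profile_loglik(ssr, n)
  ic <- information_criteria(ll, k, n)
  structure(list(model = model, estimates = estimates, se = se,
                 fitted = fitted, residual_ss = ssr, r_squared = r2,
                 adj_r_squared = adj_r2, loglik = ll, n = n, k = k,
                 criteria = ic, criteria_per_obs = ic / n,
                 converged = converged),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth-model fit:", x$model, if (!x$converged) "(NOT CONVERGED)", "\n")
  est <- rbind(estimate = x$estimates, se = x$se)
  print(round(est, 4))
  cat(sprintf("R2 = %.4f  adj.R2 = %.4f  (n = %d, k = %d)\n",
              x$r_squared, x$adj_r_squared, x$n, x$k))
  cat(sprintf("AIC = %.4f  BIC = %.4f  HQ = %.4f (raw)\n",
              x$criteria["AIC"], x$criteria["BIC"], x$criteria["HQ"]))
  invisible(x)
}

growth_curve_fun <- function(model) {
  switch(model,
    logistic = function(p, t) p["K"] / (1 + p["a"] * exp(-p["b"] * t)),
    gompertz = function(p, t) p["K"] * exp(-p["a"] * exp(-p["b"] * t)),
    richards = function(p, t) p["K"] / (1 + p["a"] * exp(-p["b"] * t))^(1 / p["m"]))
}

growth_start <- function(model, times, y) {
  K0 <- max(y) * 1.02
  y1 <- max(y[1], K0 / 100)
  b0 <- 2 / max(diff(range(times)), 1e-6) * 4
  b0 <- min(max(b0, 0.05), 2)
  switch(model,
    logistic = c(K = K0, a = max(K0 / y1 - 1, 0.05), b = b0),
    gompertz = c(K = K0, a = max(log(K0 / y1), 0.05), b = b0),
    richards = c(K = K0, a = max(K0 / y1 - 1, 0.05), b = b0, m = 1))
}

# numerical standard errors from the Gaussian least-squares objective
numeric_se <- function(sse_fun, par, ssr, n) {
  k <- length(par)
  H <- try(stats::optimHess(par, sse_fun), silent = TRUE)
  if (inherits(H, "try-error")) return(rep(NA_real_, k))
  s2 <- ssr / max(n - k, 1)
  cov <- try(2 * s2 * solve(H), silent = TRUE)
  if (inherits(cov, "try-error")) return(rep(NA_real_, k))
  d <- diag(cov)
  d[!is.finite(d) | d <= 0] <- NA_real_
  sqrt(d)
}

#' Fit a classical growth model by nonlinear least squares
#'
#' Fits one of the logistic, Gompertz or Richards curves to a single mean
#' growth trajectory, with information criteria computed from the Gaussian
#' profile likelihood.
#'
#' @param model `"logistic"`, `"gompertz"` or `"richards"`.
#' @param times Observation times.
#' @param values Abundances (same length).
#' @return A `growth_fit` report: estimates with standard errors, R^2,
#'   adjusted R^2, AIC/BIC/HQ (raw and per observation), convergence flag.
#' @export
fit_growth_model <- function(model = c("logistic", "gompertz", "richards"),
                             times, values) {
  model <- match.arg(model)
  stopifnot(length(times) == length(values))
  fun <- growth_curve_fun(model)
  start <- growth_start(model, times, values)
  if (length(values) < length(start) + 1)
    stop("need at least k + 1 observations")
  sse <- function(p) {
    names(p) <- names(start)
    f <- fun(p, times)
    if (any(!is.finite(f))) return(1e10)
    sum((values - f)^2)
  }
  opt <- stats::optim(start, sse, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  opt2 <- stats::optim(opt$par, sse, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-12))
  par <- setNames(opt2$par, names(start))
  fitted <- fun(par, times)
  se <- numeric_se(sse, par, opt2$value, length(values))
  make_fit_report(model, par, setNames(se, names(start)), values, fitted,
                  length(start), opt2$convergence == 0)
}

#' Fit the coupled two-species growth system by least squares
#'
#' Fits the six parameters of the Holling type II coupled system jointly to
#' a pair of mean curves (both species in co-culture), with the initial
#' states fixed at the first observations.
#'
#' @param times Observation times.
#' @param E_values,S_values Mean abundances of the two species.
#' @param step RK4 step.
#' @return A `growth_fit` report over the pooled 2T observations (k = 6).
#' @export
fit_coupled_growth <- function(times, E_values, S_values, step = 0.01) {
  stopifnot(length(times) == length(E_values),
            length(times) == length(S_values))
  y <- c(E_values, S_values)
  init <- c(max(E_values[1], 1e-3), max(S_values[1], 1e-3))
  trans <- function(p) c(exp(p[1]), exp(p[2]), p[3], exp(p[4]), exp(p[5]), p[6])
  sse <- function(p) {
    th <- trans(p)
    m <- try(cpp_solve_hlv(th, init[1], init[2], as.numeric(times), step),
             silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    sum((y - c(m[, 1], m[, 2]))^2)
  }
  rkE <- logistic_start(times, E_values, E_values[1])
  rkS <- logistic_start(times, S_values, S_values[1])
  p0 <- c(log(rkE["r"]), log(rkE["K"]), 0, log(rkS["r"]), log(rkS["K"]), 0)
  opt <- stats::optim(p0, sse, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  opt <- stats::optim(opt$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  par <- setNames(trans(opt$par), theta_names())
  m <- cpp_solve_hlv(par, init[1], init[2], as.numeric(times), step)
  fitted <- c(m[, 1], m[, 2])
  se_t <- numeric_se(sse, opt$par, opt$value, length(y))
  make_fit_report("coupled_holling", par, setNames(se_t, theta_names()),
                  y, fitted, 6L, opt$convergence == 0)
}

#' Compare classical and coupled growth models on co-culture mean curves
#'
#' Fits the logistic, Gompertz and Richards curves to each species' mean
#' curve separately and the coupled Holling type II system to both curves
#' jointly, and tabulates goodness of fit and information criteria (pooled
#' over the two species; classical models contribute one fit per species).
#'
#' @param times Observation times.
#' @param E_values,S_values Mean abundance curves of the two species.
#' @param step RK4 step for the coupled fit.
#' @return A data frame, one row per model, with columns `model`, `k`,
#'   `n`, `r_squared`, `AIC`, `BIC`, `HQ` (raw) and per-observation
#'   variants; the individual reports are in `attr(, "fits")`.
#' @export
compare_growth_models <- function(times, E_values, S_values, step = 0.01) {
  y <- c(E_values, S_values)
  n <- length(y)
  fits <- list()
  rows <- list()
  for (model in c("logistic", "gompertz", "richards")) {
    fE <- fit_growth_model(model, times, E_values)
    fS <- fit_growth_model(model, times, S_values)
    fits[[model]] <- list(E = fE, S = fS)
    ll <- gaussian_profile_loglik(fE$residual_ss + fS$residual_ss, n)
    k <- fE$k + fS$k
    ic <- information_criteria(ll, k, n)
    rows[[model]] <- data.frame(model = model, k = k, n = n,
                                r_squared = r_squared(y, c(fE$fitted, fS$fitted)),
                                AIC = ic["AIC"], BIC = ic["BIC"], HQ = ic["HQ"])
  }
  fc <- fit_coupled_growth(times, E_values, S_values, step)
  fits$coupled_holling <- fc
  rows$coupled_holling <- data.frame(model = "coupled_holling", k = fc$k, n = n,
                                     r_squared = fc$r_squared,
                                     AIC = fc$criteria["AIC"],
                                     BIC = fc$criteria["BIC"],
                                     HQ = fc$criteria["HQ"])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$AIC_per_obs <- out$AIC / out$n
  out$BIC_per_obs <- out$BIC / out$n
  out$HQ_per_obs <- out$HQ / out$n
  attr(out, "fits") <- fits
  out
}
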