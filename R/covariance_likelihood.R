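#' Parameters of the bivariate SAD(1) longitudinal covariance
#'
#' First-order structured antedependence: the residual of each species at
#' time index t is `phi` times its residual at t-1 plus an innovation,
#' `e_k(t) = phi_k e_k(t-1) + eps_k(t)` with `e_k(1) = eps_k(1)`.
#' Innovations have standard deviation `nu_k` and cross-species correlation
#' `rho` at equal times, zero otherwise.  This yields a nonstationary
#' covariance whose within-species variance accumulates over time.
#'
#' @param phi_e,phi_s Antedependence coefficients (dimensionless).
#' @param nu_e,nu_s Innovation standard deviations (> 0).
#' @param rho Cross-species innovation correlation, in \[-1, 1\].
#' @return An object of class `sad_params`.
#' @export
sad_params <- function(phi_e, phi_s, nu_e, nu_s, rho) {
  x <- c(phi_e = phi_e, phi_s = phi_s, nu_e = nu_e, nu_s = nu_s, rho = rho)
  if (!all(is.finite(x))) stop("all SAD parameters must be finite")
  if (nu_e <= 0 || nu_s <= 0) stop("innovation SDs nu_e, nu_s must be positive")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  structure(as.list(x), class = "sad_params")
}

as_sad_vec <- function(sad) {
  if (is.list(sad)) sad <- unlist(sad[c("phi_e", "phi_s", "nu_e", "nu_s", "rho")])
  stopifnot(length(sad) == 5L)
  unname(sad)
}

#' Bivariate SAD(1) covariance matrix
#'
#' Builds the 2T x 2T covariance of the stacked (species E, species S)
#' longitudinal residual vector implied by the SAD(1) recursion, with
#' within-species variance/covariance blocks on the diagonal and the
#' cross-species covariance blocks off the diagonal.
#'
#' @param sad A [sad_params()] object.
#' @param n_times Number of time points T (>= 1).
#' @return A 2T x 2T symmetric positive-definite matrix ordered
#'   (E block, S block).
#' @export
sad1_covariance <- function(sad, n_times) {
  if (n_times < 1) stop("n_times must be >= 1")
  if (!inherits(sad, "sad_params")) sad <- do.call(sad_params, as.list(as_sad_vec(sad)))
  s <- as_sad_vec(sad)
  cpp_sad1_cov(s[1], s[2], s[3], s[4], s[5], as.integer(n_times))
}

# univariate (single-species) SAD(1) covariance
sad1_covariance_uni <- function(phi, nu, n_times) {
  if (nu <= 0) stop("nu must be positive")
  cpp_sad1_cov_uni(phi, nu, as.integer(n_times))
}

#' Genotype-combination model
#'
#' Couples one set of growth parameters per genotype combination with a
#' single SAD(1) covariance shared across combinations.
#'
#' @param theta Named list: one [hlv_params()] (or named 6-vector) per
#'   genotype combination, e.g. `list(AB = ..., Ab = ..., aB = ..., ab = ...)`.
#' @param sad A [sad_params()] object.
#' @return An object of class `hlv_genotype_model`.
#' @export
genotype_model <- function(theta, sad) {
  if (is.null(names(theta)) || any(names(theta) == ""))
    stop("theta must be a named list, one entry per genotype combination")
  th <- t(vapply(theta, as_theta_vec, numeric(6)))
  colnames(th) <- theta_names()
  if (!inherits(sad, "sad_params")) sad <- do.call(sad_params, as.list(as_sad_vec(sad)))
  structure(list(theta = th, sad = sad), class = "hlv_genotype_model")
}

#' Genotype-specific mean curves
#'
#' Solves the growth system under each combination's parameters, returning
#' the mean vectors that enter the longitudinal likelihood.  In monoculture
#' mode the interaction scalars are ignored and each species follows its
#' standalone logistic trajectory.
#'
#' @param model An [genotype_model()] object.
#' @param times Observation times.
#' @param init Initial state `c(E0, S0)` shared by all combinations, or a
#'   2 x J matrix (one column per combination).
#' @param mode `"coculture"` (coupled system) or `"monoculture"`
#'   (interaction scalars set to zero).
#' @param step RK4 step.
#' @return A named list of data frames (`time`, `E`, `S`), one per
#'   combination.
#' @export
genotype_mean_curves <- function(model, times, init,
                                 mode = c("coculture", "monoculture"),
                                 step = 0.01) {
  stopifnot(inherits(model, "hlv_genotype_model"))
  mode <- match.arg(mode)
  J <- nrow(model$theta)
  if (is.matrix(init)) stopifnot(nrow(init) == 2L, ncol(init) == J)
  else init <- matrix(init, nrow = 2, ncol = J)
  out <- vector("list", J)
  names(out) <- rownames(model$theta)
  for (j in seq_len(J)) {
    th <- model$theta[j, ]
    if (mode == "monoculture") th[c("alpha_es", "alpha_se")] <- 0
    out[[j]] <- solve_hlv(th, init[, j], times, step)
  }
  out
}

# Sufficient statistics of the Gaussian likelihood: class sizes, class mean
# vectors and the pooled within-class scatter matrix.
make_suffstats <- function(Y, assignment, times) {
  assignment <- droplevels(as.factor(assignment))
  if (nrow(Y) != length(assignment))
    stop("assignment length must match the number of rows of Y")
  if (any(!is.finite(Y))) stop("abundance matrix contains non-finite values")
  lev <- levels(assignment)
  nj <- as.numeric(table(assignment))
  ybar <- vapply(lev, function(l) colMeans(Y[assignment == l, , drop = FALSE]),
                 numeric(ncol(Y)))
  S <- matrix(0, ncol(Y), ncol(Y))
  for (l in lev) {
    Yl <- Y[assignment == l, , drop = FALSE]
    S <- S + crossprod(sweep(Yl, 2, colMeans(Yl)))
  }
  list(Y = Y, assignment = assignment, levels = lev, nj = nj,
       ybar = ybar, S = S, times = as.numeric(times))
}

#' Joint log-likelihood of paired longitudinal abundance data
#'
#' Sum over individuals of the 2T-dimensional normal log-density with
#' genotype-combination-specific mean curves (solved from the growth
#' system) and a shared SAD(1) covariance.
#'
#' @param Y Numeric matrix, one row per individual (pair), columns ordered
#'   as (E at each time, then S at each time).
#' @param assignment Factor assigning each row to a genotype combination;
#'   levels must match the combinations of `model`.
#' @param model An [genotype_model()] object.
#' @param times Observation times (length `ncol(Y)/2`).
#' @param init Optional initial states (2 x J matrix, columns in the order
#'   of `rownames(model$theta)`); defaults to each combination's observed
#'   mean abundance at the first time.
#' @param step RK4 step.
#' @return The joint log-likelihood (scalar).
#' @export
joint_log_likelihood <- function(Y, assignment, model, times, init = NULL,
                                 step = 0.01) {
  stopifnot(inherits(model, "hlv_genotype_model"))
  times <- check_times(times)
  T <- length(times)
  if (ncol(Y) != 2L * T) stop("Y must have 2 * length(times) columns")
  assignment <- as.factor(assignment)
  if (any(is.na(assignment))) stop("every observation must be assigned to a combination")
  combos <- rownames(model$theta)
  if (!all(levels(droplevels(assignment)) %in% combos))
    stop("assignment contains combinations not declared in the model: ",
         paste(setdiff(levels(droplevels(assignment)), combos), collapse = ", "))
  assignment <- factor(assignment, levels = combos)
  st <- make_suffstats(Y, assignment, times)
  keep <- match(st$levels, combos)
  theta <- model$theta[keep, , drop = FALSE]
  if (is.null(init)) init <- default_init_cc(st)
  else init <- init[, keep, drop = FALSE]
  nll <- cpp_nll_cc(theta, as_sad_vec(model$sad), st$ybar, st$nj, st$S,
                    st$times, init, step)
  if (nll >= 1e10) stop("likelihood not computable (singular covariance or diverging trajectory)")
  -nll
}

# observed per-combination initial states, clamped away from zero so the
# logistic term cannot start on the wrong side of the unstable fixed point
default_init_cc <- function(st) {
  T <- length(st$times)
  init <- rbind(st$ybar[1, ], st$ybar[T + 1, ])
  pmax(init, 1e-6)
}

default_init_mono <- function(st) pmax(st$ybar[1, ], 1e-6)

## ---- maximum-likelihood fitting ------------------------------------------

#' Optimizer settings for the Nelder-Mead + RK4 hybrid estimator
#'
#' @param restarts Number of Nelder-Mead starts: the first is the
#'   deterministic data-driven start (or a supplied warm start), the rest
#'   are jittered copies of it.
#' @param maxit Maximum simplex iterations per cycle.
#' @param cycles Simplex restarts per start (re-running Nelder-Mead from
#'   its own solution rebuilds the simplex and escapes premature collapse).
#' @param reltol Relative convergence tolerance of the simplex.
#' @param step RK4 integration step used inside the likelihood (hours).
#' @param jitter SD of the normal jitter applied to transformed parameters
#'   for restarts 2..restarts.
#' @param init How initial abundances are handled: `"shared"` (default)
#'   estimates one initial state per species, shared by all combinations
#'   under both hypotheses (inocula are standardized, so the genotype test
#'   concerns the dynamic parameters only and the null stays exactly
#'   nested); `"observed"` fixes them at each combination's observed mean
#'   at the first time (only sensible when early-time noise is small);
#'   `"per_combination"` estimates one per combination (sensitivity
#'   analysis).
#' @param block_rounds Rounds of block-coordinate refinement after the
#'   joint search: each round optimizes every combination's free
#'   parameters against the current covariance (a cheap one-trajectory
#'   subproblem), then the shared/SAD/init block, then polishes jointly.
#'   0 disables.
#' @param block_maxit Simplex iterations per block subproblem.
#' @param polish `"bfgs"` (default) finishes with a quasi-Newton polish
#'   using numerical gradients, which traverses the curved ridges (initial
#'   state vs growth rate vs interaction scalar) that stall simplex
#'   coordinate search; `"none"` keeps the pure simplex path.
#' @param polish_maxit Iterations of the polish stage.
#' @return A list of class `hlv_fit_control`.
#' @export
hlv_fit_control <- function(restarts = 10, maxit = 5000, cycles = 2,
                            reltol = 1e-8, step = 0.3, jitter = 0.3,
                            init = c("shared", "observed", "per_combination"),
                            block_rounds = 2, block_maxit = 500,
                            polish = c("bfgs", "none"), polish_maxit = 200) {
  init <- match.arg(init)
  polish <- match.arg(polish)
  structure(list(restarts = restarts, maxit = maxit, cycles = cycles,
                 reltol = reltol, step = step, jitter = jitter,
                 init = init, block_rounds = block_rounds,
                 block_maxit = block_maxit, polish = polish,
                 polish_maxit = polish_maxit),
            class = "hlv_fit_control")
}

# model descriptors used by the shared fitting core ------------------------

cc_descriptor <- function() {
  list(
    kind = "coculture",
    kind_code = 1L,
    k_theta = 6L,
    theta_names = theta_names(),
    theta_log = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    sad_names = c("phi_e", "phi_s", "nu_e", "nu_s", "rho"),
    sad_to_x = function(s) c(atanh(pmin(pmax(s[1:2] / 3, -0.999), 0.999)),
                             log(s[3:4]), atanh(pmin(pmax(s[5], -0.99), 0.99))),
    x_to_sad = function(x) c(3 * tanh(x[1:2]), exp(x[3:4]), tanh(x[5])),
    nll = function(theta, sad, st, init, step)
      cpp_nll_cc(theta, sad, st$ybar, st$nj, st$S, st$times, init, step),
    mu_one = function(theta_row, init_col, times, step) {
      m <- tryCatch(cpp_solve_hlv(theta_row, init_col[1], init_col[2], times, step),
                    error = function(e) NULL)
      if (is.null(m)) NULL else c(m[, 1], m[, 2])
    },
    sigma_fun = function(sad, T)
      cpp_sad1_cov(sad[1], sad[2], sad[3], sad[4], sad[5], T),
    default_init = default_init_cc,
    n_species = 2L
  )
}

mono_descriptor <- function() {
  list(
    kind = "monoculture",
    kind_code = 2L,
    k_theta = 2L,
    theta_names = c("r", "K"),
    theta_log = c(TRUE, TRUE),
    sad_names = c("phi", "nu"),
    sad_to_x = function(s) c(atanh(pmin(pmax(s[1] / 3, -0.999), 0.999)), log(s[2])),
    x_to_sad = function(x) c(3 * tanh(x[1]), exp(x[2])),
    nll = function(theta, sad, st, init, step)
      cpp_nll_mono(theta, sad, st$ybar, st$nj, st$S, st$times, init, step),
    mu_one = function(theta_row, init_col, times, step) {
      m <- tryCatch(cpp_solve_hlv(c(theta_row, 0, 1, 1, 0), init_col[1], 0,
                                  times, step),
                    error = function(e) NULL)
      if (is.null(m)) NULL else m[, 1]
    },
    sigma_fun = function(sad, T) cpp_sad1_cov_uni(sad[1], sad[2], T),
    default_init = default_init_mono,
    n_species = 1L
  )
}

# pack/unpack between the transformed optimizer vector and (theta, sad, init)
make_packer <- function(desc, J, share, init_mode) {
  shared <- desc$theta_names %in% share
  sizes <- ifelse(shared, 1L, J)
  offs <- cumsum(c(0L, sizes))
  n_theta_par <- offs[length(offs)]
  n_sad <- length(desc$sad_names)
  n_init <- switch(init_mode, observed = 0L, shared = desc$n_species,
                   per_combination = J * desc$n_species)
  list(
    n_par = n_theta_par + n_sad + n_init,
    pack = function(theta, sad, init = NULL) {
      x <- numeric(n_theta_par)
      for (e in seq_len(desc$k_theta)) {
        tv <- theta[, e]
        if (desc$theta_log[e]) tv <- log(tv)
        v <- if (shared[e]) mean(tv) else tv
        x[(offs[e] + 1L):offs[e + 1L]] <- v
      }
      out <- c(x, desc$sad_to_x(sad))
      if (init_mode == "shared")
        out <- c(out, log(pmax(rowMeans(init), 0.01)))
      else if (init_mode == "per_combination")
        out <- c(out, log(pmax(as.numeric(init), 0.01)))
      out
    },
    unpack = function(par) {
      theta <- matrix(0, J, desc$k_theta)
      for (e in seq_len(desc$k_theta)) {
        v <- par[(offs[e] + 1L):offs[e + 1L]]
        if (desc$theta_log[e]) v <- exp(v)
        theta[, e] <- v
      }
      sad <- desc$x_to_sad(par[(n_theta_par + 1L):(n_theta_par + n_sad)])
      init <- NULL
      if (n_init > 0L) {
        iv <- exp(par[(n_theta_par + n_sad + 1L):(n_theta_par + n_sad + n_init)])
        init <- matrix(iv, nrow = desc$n_species, ncol = J)
      }
      list(theta = theta, sad = sad, init = init)
    },
    n_free = n_theta_par + n_sad + n_init,
    # step scale per packed coordinate: ~10% moves for log-transformed
    # parameters, much finer moves for the interaction scalars
    parscale = {
      th_sc <- unlist(lapply(seq_len(desc$k_theta), function(e)
        rep(if (desc$theta_log[e]) 0.1 else 0.01, sizes[e])))
      sad_sc <- rep(0.1, n_sad)
      c(th_sc, sad_sc, rep(0.1, n_init))
    },
    # 0-based layout metadata for the C++ packed-objective evaluator
    meta = list(theta_off = as.integer(offs[-length(offs)]),
                theta_shared = as.integer(shared),
                theta_log = as.integer(desc$theta_log),
                sad_off = as.integer(n_theta_par),
                init_off = as.integer(n_theta_par + n_sad)),
    # block-coordinate structure: per-combination free theta coordinates,
    # and the complementary shared/SAD/init coordinates
    free_entries = which(!shared),
    combo_idx = function(j) offs[which(!shared)] + j,
    rest_idx = {
      sh <- unlist(lapply(which(shared), function(e) (offs[e] + 1L):offs[e + 1L]))
      c(sh, seq(n_theta_par + 1L, n_theta_par + n_sad + n_init))
    }
  )
}

# crude logistic least squares on a mean curve: grid search over (r, K)
# with the initial value fixed, used only to seed the optimizer
logistic_start <- function(times, y, x0) {
  ymax <- max(y)
  if (ymax <= 0) return(c(r = 0.3, K = 1))
  Ks <- ymax * c(0.9, 1.0, 1.1, 1.3)
  Ks <- Ks[Ks > 0]
  rs <- exp(seq(log(0.03), log(2), length.out = 24))
  best <- c(r = 0.3, K = ymax)
  best_sse <- Inf
  for (K in Ks) for (r in rs) {
    sse <- sum((y - logistic_closed_form(r, K, max(x0, 1e-3), times))^2)
    if (sse < best_sse) { best_sse <- sse; best <- c(r = r, K = K) }
  }
  best
}

# deterministic data-driven starting values on the natural scale
start_values <- function(desc, st, J) {
  T <- length(st$times)
  n <- sum(st$nj)
  denom <- max(n - J, 1)
  if (desc$kind == "coculture") {
    theta <- matrix(0, J, 6L)
    for (j in seq_len(J)) {
      rkE <- logistic_start(st$times, st$ybar[1:T, j], st$ybar[1, j])
      rkS <- logistic_start(st$times, st$ybar[(T + 1):(2 * T), j], st$ybar[T + 1, j])
      theta[j, ] <- c(rkE["r"], rkE["K"], 0, rkS["r"], rkS["K"], 0)
    }
    nu_e <- sqrt(max(st$S[1, 1] / denom, 1e-4))
    nu_s <- sqrt(max(st$S[T + 1, T + 1] / denom, 1e-4))
    sad <- c(0.5, 0.5, nu_e, nu_s, 0)
  } else {
    theta <- matrix(0, J, 2L)
    for (j in seq_len(J)) theta[j, ] <- logistic_start(st$times, st$ybar[, j], st$ybar[1, j])
    sad <- c(0.5, sqrt(max(st$S[1, 1] / denom, 1e-4)))
  }
  list(theta = theta, sad = sad)
}

# shared Nelder-Mead driver over restarts and simplex cycles; parscale
# keeps the initial simplex comparable across parameter types (the
# interaction scalars live on a much finer natural scale than the
# log-transformed rates and capacities)
run_nelder_mead <- function(objective, starts, control, parscale = NULL) {
  best <- NULL
  for (s in seq_along(starts)) {
    par <- starts[[s]]
    conv <- FALSE
    val <- objective(par)
    if (!is.finite(val)) next
    for (cy in seq_len(control$cycles)) {
      ctl <- list(maxit = control$maxit, reltol = control$reltol)
      if (!is.null(parscale)) ctl$parscale <- parscale
      opt <- stats::optim(par, objective, method = "Nelder-Mead", control = ctl)
      par <- opt$par
      conv <- opt$convergence == 0
      val <- opt$value
    }
    if (is.null(best) || val < best$value - 1e-12)
      best <- list(par = par, value = val, converged = conv, restart = s)
  }
  if (is.null(best)) stop("all optimizer starts failed (non-finite objective)")
  best
}

# Block-coordinate refinement: with the covariance held fixed, each
# combination's free growth parameters enter the likelihood only through
# its own mean curve, so the subproblem needs a single trajectory solve
# and a quadratic form against the Cholesky factor.  Alternating these
# cheap low-dimensional simplex searches with the shared/SAD/init block
# and a final joint polish converges far faster than a joint
# high-dimensional search alone.
refine_blocks <- function(desc, packer, st, control, par, objective,
                          obs_init = NULL) {
  J <- length(st$levels)
  T <- length(st$times)
  free_e <- packer$free_entries
  logm <- desc$theta_log[free_e]
  conv <- FALSE
  for (round in seq_len(control$block_rounds)) {
    u <- packer$unpack(par)
    init <- if (is.null(obs_init)) u$init else obs_init
    Sigma <- desc$sigma_fun(u$sad, T)
    U <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(U)) break
    for (j in seq_len(J)) {
      idx <- packer$combo_idx(j)
      th_base <- u$theta[j, ]
      d_j <- st$ybar[, j]
      w_j <- st$nj[j]
      obj_j <- function(x) {
        nat <- x
        nat[logm] <- exp(pmin(nat[logm], 50))
        th <- th_base
        th[free_e] <- nat
        mu <- desc$mu_one(th, init[, j], st$times, control$step)
        if (is.null(mu) || any(!is.finite(mu))) return(1e10)
        z <- backsolve(U, d_j - mu, transpose = TRUE)
        0.5 * w_j * sum(z * z)
      }
      oj <- stats::optim(par[idx], obj_j, method = "Nelder-Mead",
                         control = list(maxit = control$block_maxit,
                                        reltol = control$reltol,
                                        parscale = packer$parscale[idx]))
      par[idx] <- oj$par
      u$theta <- packer$unpack(par)$theta
    }
    # shared parameters, covariance and initial states given the combos
    idx <- packer$rest_idx
    obj_rest <- function(x) {
      p <- par
      p[idx] <- x
      objective(p)
    }
    orst <- stats::optim(par[idx], obj_rest, method = "Nelder-Mead",
                         control = list(maxit = control$block_maxit,
                                        reltol = control$reltol,
                                        parscale = packer$parscale[idx]))
    par[idx] <- orst$par
  }
  # joint polish
  op <- stats::optim(par, objective, method = "Nelder-Mead",
                     control = list(maxit = control$maxit,
                                    reltol = control$reltol,
                                    parscale = packer$parscale))
  list(par = op$par, value = op$value, converged = op$convergence == 0)
}

fit_core <- function(desc, Y, assignment, times, share, control, start = NULL) {
  times <- check_times(times)
  T <- length(times)
  if (ncol(Y) != desc$n_species * T)
    stop("Y must have ", desc$n_species, " * length(times) columns")
  if (all(Y == 0)) stop("degenerate input: all abundances are zero")
  assignment <- droplevels(as.factor(assignment))
  small <- table(assignment) < 2
  if (any(small))
    stop("genotype combination(s) with fewer than 2 individuals: ",
         paste(names(small)[small], collapse = ", "))
  st <- make_suffstats(Y, assignment, times)
  J <- length(st$levels)
  packer <- make_packer(desc, J, share, control$init)
  obs_init <- desc$default_init(st)
  if (desc$n_species == 1L) obs_init <- matrix(obs_init, nrow = 1)
  start_init <- pmax(obs_init, 0.05)

  init_code <- match(control$init, c("observed", "shared", "per_combination")) - 1L
  meta <- packer$meta
  objective <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 50)) return(1e10)
    cpp_nll_packed(par, desc$kind_code, J, meta$theta_off, meta$theta_shared,
                   meta$theta_log, meta$sad_off, init_code, meta$init_off,
                   st$ybar, st$nj, st$S, st$times, obs_init, control$step)
  }

  sv <- start_values(desc, st, J)
  base_par <- packer$pack(sv$theta, sv$sad, start_init)
  starts <- list(base_par)
  if (!is.null(start)) {
    # warm start (e.g. the null fit embedded in the alternative model)
    ws <- packer$pack(start$theta_full(J), start$sad, start$init_full(J))
    starts <- c(list(ws), starts)
  }
  n_extra <- max(0L, control$restarts - length(starts))
  for (i in seq_len(n_extra))
    starts[[length(starts) + 1L]] <-
      base_par + rnorm(length(base_par), sd = control$jitter)

  best <- run_nelder_mead(objective, starts, control, packer$parscale)
  if (control$block_rounds > 0 && J > 1 && length(packer$free_entries)) {
    ref <- refine_blocks(desc, packer, st, control, best$par, objective,
                         if (control$init == "observed") obs_init else NULL)
    if (ref$value < best$value) {
      best$par <- ref$par
      best$value <- ref$value
      best$converged <- ref$converged
    }
  }
  if (control$polish == "bfgs") {
    op <- tryCatch(
      stats::optim(best$par, objective, method = "BFGS",
                   control = list(maxit = control$polish_maxit,
                                  reltol = control$reltol,
                                  parscale = packer$parscale)),
      error = function(e) NULL)
    if (!is.null(op) && is.finite(op$value) && op$value < best$value) {
      best$par <- op$par
      best$value <- op$value
    }
  }
  u <- packer$unpack(best$par)
  theta <- u$theta
  rownames(theta) <- st$levels
  colnames(theta) <- desc$theta_names
  sad <- setNames(u$sad, desc$sad_names)
  init <- if (control$init == "observed") obs_init else u$init
  colnames(init) <- st$levels
  structure(list(kind = desc$kind, theta = theta, sad = sad,
                 loglik = -best$value, n_free = packer$n_free,
                 converged = best$converged, restart = best$restart,
                 share = share, init = init, times = times,
                 counts = setNames(st$nj, st$levels), control = control),
            class = "hlv_fit")
}

# warm-start helper: expand a fitted model so every combination starts at
# the (possibly shared) estimates of a previous fit
warm_start <- function(fit) {
  list(
    theta_full = function(J) {
      th <- fit$theta
      if (nrow(th) == J) th else matrix(rep(th[1, ], each = J), nrow = J)
    },
    init_full = function(J) {
      ini <- fit$init
      if (ncol(ini) == J) ini else matrix(rep(ini[, 1], J), ncol = J)
    },
    sad = unname(fit$sad)
  )
}

#' Fit the genotype-combination growth model by maximum likelihood
#'
#' Hybrid estimator: genotype-specific mean curves are solved by fixed-step
#' fourth-order Runge-Kutta inside a Nelder-Mead simplex search over
#' transformed parameters (log for rates, capacities and innovation SDs,
#' scaled atanh for antedependence coefficients and the innovation
#' correlation, identity for interaction scalars).  By default a single
#' initial state per species is estimated and shared across combinations
#' (see [hlv_fit_control()]), so the shared-curve null model is exactly
#' nested in the genotype-specific alternative and the test concerns the
#' dynamic parameters only.
#'
#' @param Y Numeric matrix, one row per pair; columns (E block, S block).
#' @param assignment Factor of genotype combinations, one per row of `Y`;
#'   every combination must contain at least 2 individuals.
#' @param times Observation times.
#' @param mode `"by_combination"` fits one parameter set per combination
#'   (the alternative hypothesis); `"null"` fits a single shared set.
#' @param share Character vector of parameter names (among
#'   `r_e, K_e, alpha_es, r_s, K_s, alpha_se`) constrained to be equal
#'   across combinations; used for the parameter-subset tests.  Ignored in
#'   `"null"` mode (all shared).
#' @param control An [hlv_fit_control()] object.
#' @param start Optional `hlv_fit` object used as a warm start (first
#'   restart), e.g. a null fit seeding the alternative fit.
#' @return An object of class `hlv_fit` with elements `theta` (J x 6
#'   matrix), `sad`, `loglik`, `n_free`, `converged`, `init`, `counts`.
#' @export
fit_hlv_model <- function(Y, assignment, times,
                          mode = c("by_combination", "null"),
                          share = character(), control = hlv_fit_control(),
                          start = NULL) {
  mode <- match.arg(mode)
  if (mode == "null") share <- theta_names()
  ws <- if (!is.null(start)) warm_start(start) else NULL
  fit <- fit_core(cc_descriptor(), Y, assignment, times, share, control, ws)
  fit$mode <- mode
  fit
}

#' Fit the single-species monoculture growth model
#'
#' As [fit_hlv_model()] but for one species in monoculture: logistic mean
#' curves (growth rate and capacity per genotype class) with univariate
#' SAD(1) residuals.
#'
#' @param Y Numeric matrix, one row per strain, one column per time point.
#' @param assignment Factor of genotype classes.
#' @param times Observation times.
#' @param mode `"by_combination"` or `"null"`.
#' @param share Parameter names (among `r`, `K`) shared across classes.
#' @param control An [hlv_fit_control()] object.
#' @param start Optional warm-start `hlv_fit`.
#' @return An `hlv_fit` object (theta columns `r`, `K`; sad `phi`, `nu`).
#' @export
fit_mono_model <- function(Y, assignment, times,
                           mode = c("by_combination", "null"),
                           share = character(), control = hlv_fit_control(),
                           start = NULL) {
  mode <- match.arg(mode)
  if (mode == "null") share <- c("r", "K")
  ws <- if (!is.null(start)) warm_start(start) else NULL
  fit <- fit_core(mono_descriptor(), Y, assignment, times, share, control, ws)
  fit$mode <- mode
  fit
}

#' @export
print.hlv_fit <- function(x, ...) {
  cat("Maximum-likelihood fit (", x$kind, ", mode = ", x$mode, ")\n", sep = "")
  cat("log-likelihood:", format(x$loglik, digits = 8),
      " free parameters:", x$n_free,
      " converged:", x$converged, "\n")
  cat("combination parameters:\n")
  print(round(x$theta, 4))
  cat("SAD(1):", paste(names(x$sad), round(x$sad, 4), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param fit An `hlv_fit` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to `path`.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "hlv_fit"))
  obj <- list(
    kind = fit$kind, mode = fit$mode,
    combinations = lapply(seq_len(nrow(fit$theta)), function(j) as.list(fit$theta[j, ])),
    sad = as.list(fit$sad),
    loglik = fit$loglik, n_free = fit$n_free, converged = fit$converged
  )
  names(obj$combinations) <- rownames(fit$theta)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
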