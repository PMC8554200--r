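# Shared fixtures: everything is generated in code at test time.

times16 <- function() seq(0, 36, length.out = 16)

base_theta <- function()
  c(r_e = 0.5, K_e = 24, alpha_es = -0.05, r_s = 0.4, K_s = 21.5,
    alpha_se = -0.1)

# optimizer settings for tests: small budgets, block refinement on
fast_control <- function(...)
  do.call(hlv_fit_control,
          utils::modifyList(list(restarts = 1, maxit = 300, cycles = 2,
                                 block_rounds = 2, block_maxit = 250,
                                 polish = "none"),
                            list(...)))

accurate_control <- function(...)
  do.call(hlv_fit_control,
          utils::modifyList(list(restarts = 2, maxit = 2000, cycles = 2,
                                 block_rounds = 2, block_maxit = 500,
                                 polish = "bfgs"),
                            list(...)))

# very small budget for bulk monoculture scans (permutation calibration)
mono_control <- function()
  hlv_fit_control(restarts = 1, maxit = 200, cycles = 2, block_rounds = 1,
                  block_maxit = 150, polish = "none")

# four-combination co-culture data with explicit parameter sets per combo
make_combo_data <- function(theta, n_per = 12, sad = sad_params(0.6, 0.6, 0.8, 0.8, 0.2),
                            times = times16(), init = c(0.5, 0.5), seed = 1) {
  set.seed(seed)
  T <- length(times)
  mu <- sapply(rownames(theta), function(j) {
    m <- solve_hlv(theta[j, ], init, times, 0.05)
    c(m$E, m$S)
  })
  Y <- do.call(rbind, lapply(rownames(theta), function(j)
    matrix(rep(mu[, j], n_per), n_per, byrow = TRUE)))
  Y <- Y + sad_residuals(nrow(Y), sad, T)
  list(Y = Y, assignment = factor(rep(rownames(theta), each = n_per),
                                  levels = rownames(theta)),
       times = times, mu = mu)
}

# independent SAD(1) residual generator (kept in test code so package
# internals are not their own oracle)
sad_residuals <- function(n, sad, T) {
  s <- unlist(sad[c("phi_e", "phi_s", "nu_e", "nu_s", "rho")])
  z1 <- matrix(rnorm(n * T), n, T)
  z2 <- matrix(rnorm(n * T), n, T)
  eps_e <- s[3] * z1
  eps_s <- s[4] * (s[5] * z1 + sqrt(1 - s[5]^2) * z2)
  e_e <- eps_e; e_s <- eps_s
  for (t in 2:T) {
    e_e[, t] <- s[1] * e_e[, t - 1] + eps_e[, t]
    e_s[, t] <- s[2] * e_s[, t - 1] + eps_s[, t]
  }
  cbind(e_e, e_s)
}

small_sim_config <- function(...)
  sim_config(n_pairs = 20, n_markers = 6, causal_marker_A = 3,
             causal_marker_B = 4, ...)
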