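test_that("SAD(1) covariance matches a direct double-loop reference", {
  # independent reference: brute-force evaluation of the recursion's
  # covariance sums
  ref_cov <- function(phi_e, phi_s, nu_e, nu_s, rho, T) {
    S <- matrix(0, 2 * T, 2 * T)
    for (j in 1:T) for (k in 1:T) {
      for (m in 1:min(j, k)) {
        S[j, k] <- S[j, k] + nu_e^2 * phi_e^(j - m) * phi_e^(k - m)
        S[T + j, T + k] <- S[T + j, T + k] + nu_s^2 * phi_s^(j - m) * phi_s^(k - m)
        S[j, T + k] <- S[j, T + k] + rho * nu_e * nu_s * phi_e^(j - m) * phi_s^(k - m)
        S[T + j, k] <- S[T + j, k] + rho * nu_e * nu_s * phi_s^(j - m) * phi_e^(k - m)
      }
    }
    S
  }
  set.seed(3)
  for (i in 1:10) {
    s <- sad_params(runif(1, -0.9, 0.9), runif(1, -0.9, 0.9),
                    runif(1, 0.3, 2), runif(1, 0.3, 2), runif(1, -0.8, 0.8))
    T <- sample(2:6, 1)
    M <- sad1_covariance(s, T)
    expect_equal(M, ref_cov(s$phi_e, s$phi_s, s$nu_e, s$nu_s, s$rho, T),
                 tolerance = 1e-12)
    expect_equal(M, t(M))
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("uncorrelated white SAD(1) reduces to block-diagonal variances", {
  M <- sad1_covariance(sad_params(0, 0, 1, 2, 0), 3)
  expect_equal(M, diag(c(1, 1, 1, 4, 4, 4)))
})

test_that("SAD(1) covariance matches the Monte-Carlo covariance of its recursion", {
  s <- sad_params(0.5, 0.3, 1, 2, 0.4)
  T <- 4
  N <- 2e5
  set.seed(99)
  E <- sad_residuals(N, s, T)
  emp <- cov(E)
  Sig <- sad1_covariance(s, T)
  # elementwise Monte-Carlo SE of a covariance entry
  se <- sqrt((outer(diag(Sig), diag(Sig)) + Sig^2) / N)
  expect_true(all(abs(emp - Sig) < 3.5 * se))
})

test_that("joint log-likelihood equals the dense multivariate-normal oracle", {
  set.seed(21)
  T <- 3; n <- 4
  times <- c(0, 5, 10)
  th <- list(A = c(0.5, 10, -0.05, 0.4, 8, -0.1),
             a = c(0.6, 12, 0.02, 0.35, 9, -0.02))
  model <- genotype_model(th, sad_params(0.4, 0.6, 0.7, 0.9, 0.3))
  Y <- matrix(rnorm(n * 2 * T, mean = 5, sd = 2), n)
  asg <- factor(c("A", "A", "a", "a"), levels = c("A", "a"))
  init <- matrix(c(0.5, 0.5), 2, 2)
  ll <- joint_log_likelihood(Y, asg, model, times, init = init, step = 0.01)
  # dense oracle: per-individual 2T-dimensional normal log-density
  Sig <- sad1_covariance(model$sad, T)
  mu <- sapply(names(th), function(j) {
    m <- solve_hlv(th[[j]], c(0.5, 0.5), times, 0.01)
    c(m$E, m$S)
  })
  dens <- sum(sapply(seq_len(n), function(i) {
    d <- Y[i, ] - mu[, as.character(asg[i])]
    -0.5 * (2 * T * log(2 * pi) + determinant(Sig)$modulus[1] +
              t(d) %*% solve(Sig) %*% d)
  }))
  expect_equal(ll, dens, tolerance = 1e-8)

  # additivity: duplicating one individual adds exactly its log-density
  ll2 <- joint_log_likelihood(rbind(Y, Y[1, ]), factor(c(as.character(asg), "A"),
                                                       levels = c("A", "a")),
                              model, times, init = init, step = 0.01)
  d1 <- Y[1, ] - mu[, "A"]
  ld1 <- -0.5 * (2 * T * log(2 * pi) + determinant(Sig)$modulus[1] +
                   t(d1) %*% solve(Sig) %*% d1)
  expect_equal(ll2 - ll, as.numeric(ld1), tolerance = 1e-8)
})

test_that("with fixed covariance the per-class sample mean maximizes the likelihood", {
  set.seed(8)
  T <- 4; n <- 12
  Sig <- sad1_covariance(sad_params(0.5, 0.5, 1, 1, 0.2), T)
  Y <- matrix(rnorm(n * 2 * T, 6, 1.5), n)
  ybar <- colMeans(Y)
  quadsum <- function(mu) {
    Si <- solve(Sig)
    sum(apply(Y, 1, function(y) t(y - mu) %*% Si %*% (y - mu)))
  }
  q0 <- quadsum(ybar)
  for (i in 1:10) expect_gt(quadsum(ybar + rnorm(2 * T, sd = 0.3)), q0)
})

test_that("parameters are recovered from near-noiseless data", {
  th <- rbind(AB = c(0.54, 25.4, -0.08, 0.44, 22.9, -0.16),
              Ab = c(0.54, 25.4, -0.05, 0.40, 21.6, -0.10),
              aB = c(0.50, 23.9, -0.08, 0.44, 22.9, -0.16),
              ab = c(0.50, 23.9, -0.05, 0.40, 21.6, -0.10))
  colnames(th) <- c("r_e", "K_e", "alpha_es", "r_s", "K_s", "alpha_se")
  times <- times16()
  mu <- sapply(rownames(th), function(j) {
    m <- solve_hlv(th[j, ], c(0.5, 0.5), times, 0.01)
    c(m$E, m$S)
  })
  set.seed(7)
  n_per <- 5
  Y <- do.call(rbind, lapply(rownames(th), function(j)
    matrix(rep(mu[, j], n_per), n_per, byrow = TRUE)))
  Y <- Y + matrix(rnorm(length(Y), sd = 1e-3), nrow(Y))
  asg <- factor(rep(rownames(th), each = n_per), levels = rownames(th))
  fit <- fit_hlv_model(Y, asg, times,
                       control = accurate_control(step = 0.1))
  expect_lt(max(abs((fit$theta - th) / th)), 0.01)
  expect_equal(unname(fit$init[, 1]), c(0.5, 0.5), tolerance = 0.01)
})

test_that("the genotype-specific model never fits worse than the shared model", {
  th0 <- base_theta()
  th <- rbind(AB = th0, Ab = th0, aB = th0, ab = th0)
  d <- make_combo_data(th, n_per = 10, seed = 31)
  f0 <- fit_hlv_model(d$Y, d$assignment, d$times, mode = "null",
                      control = fast_control())
  f1 <- fit_hlv_model(d$Y, d$assignment, d$times, mode = "by_combination",
                      control = fast_control(), start = f0)
  expect_gte(f1$loglik, f0$loglik - 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  times <- times16()
  Y <- matrix(0, 8, 32)
  asg <- factor(rep(c("A", "a"), each = 4))
  expect_error(fit_hlv_model(Y, asg, times), "all abundances are zero")
  Y2 <- matrix(rnorm(8 * 32, 5), 8)
  asg2 <- factor(c(rep("A", 7), "a"))
  expect_error(fit_hlv_model(Y2, asg2, times), "fewer than 2 individuals.*a")
  model <- genotype_model(list(A = base_theta(), a = base_theta()),
                          sad_params(0.5, 0.5, 1, 1, 0))
  expect_error(joint_log_likelihood(Y2, factor(rep(c("A", "B"), 4)), model,
                                    times),
               "not declared")
})

test_that("monoculture mean curves ignore the interaction scalars", {
  model <- genotype_model(list(A = c(0.5, 24, -0.4, 0.4, 21, -0.4),
                               a = c(0.5, 24, 0, 0.4, 21, 0)),
                          sad_params(0.5, 0.5, 1, 1, 0))
  cv <- genotype_mean_curves(model, times16(), c(0.5, 0.5),
                             mode = "monoculture", step = 0.05)
  expect_equal(cv$A$E, cv$a$E, tolerance = 1e-12)
  expect_equal(cv$A$S, cv$a$S, tolerance = 1e-12)
  # in co-culture a harmful alpha lowers the focal species' curve
  cc <- genotype_mean_curves(model, times16(), c(0.5, 0.5), step = 0.05)
  expect_true(all(cc$A$E[-1] < cc$a$E[-1]))
})
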