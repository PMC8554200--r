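test_that("right-hand side evaluates the coupled growth equations", {
  p <- hlv_params(r_e = 0.5, K_e = 24, alpha_es = -0.01,
                  r_s = 0.4, K_s = 21, alpha_se = -0.02)
  # zero abundance is a fixed point
  expect_equal(unname(hlv_rhs(c(0, 0), p)), c(0, 0))
  # with no interaction, the logistic equilibrium is a fixed point
  p0 <- hlv_params(0.5, 24, 0, 0.4, 21, 0)
  expect_equal(unname(hlv_rhs(c(24, 21), p0)), c(0, 0))
  # hand-evaluated derivative pair at E = S = 5
  d <- hlv_rhs(c(5, 5), p)
  expect_equal(unname(d), c(1.9583333, 1.4904762), tolerance = 1e-6)
  expect_error(hlv_rhs(c(NA, 1), p), "finite")
  expect_error(hlv_rhs(c(-1, 1), p), "non-negative")
})

test_that("interaction term carries the sign of its scalar", {
  set.seed(11)
  for (i in 1:20) {
    a_es <- runif(1, -0.5, 0.5); a_se <- runif(1, -0.5, 0.5)
    st <- runif(2, 0.5, 20)
    p1 <- hlv_params(0.5, 24, a_es, 0.4, 21, a_se)
    p0 <- hlv_params(0.5, 24, 0, 0.4, 21, 0)
    delta <- hlv_rhs(st, p1) - hlv_rhs(st, p0)
    expect_equal(sign(delta[["dE"]]), sign(a_es))
    expect_equal(sign(delta[["dS"]]), sign(a_se))
  }
})

test_that("RK4 solution matches the logistic closed form when alpha = 0", {
  times <- seq(0, 30, length.out = 13)
  for (r in c(0.1, 0.4, 0.8)) for (K in c(5, 24)) for (x0 in c(0.2, 1, 3)) {
    s <- solve_hlv(c(r, K, 0, r, K, 0), c(x0, x0), times, step = 0.01)
    cf <- K * x0 * exp(r * times) / (K + x0 * (exp(r * times) - 1))
    expect_lt(max(abs(s$E - cf)), 1e-6)
    expect_lt(max(abs(s$S - cf)), 1e-6)
  }
})

test_that("zero growth rate gives a constant trajectory", {
  s <- solve_hlv(c(0, 24, 0, 0, 21, 0), c(2, 3),
                 seq(0, 36, by = 6), step = 0.1)
  expect_equal(s$E, rep(2, 7), tolerance = 1e-12)
  expect_equal(s$S, rep(3, 7), tolerance = 1e-12)
})

test_that("RK4 global error scales as the fourth power of the step", {
  p <- c(0.6, 24, -0.08, 0.5, 21.5, -0.2)
  times <- seq(0, 36, by = 2.4)
  ref <- solve_hlv(p, c(0.5, 0.5), times, step = 0.01)
  e1 <- max(abs(as.matrix(solve_hlv(p, c(0.5, 0.5), times, step = 1.2)[, 2:3]) -
                as.matrix(ref[, 2:3])))
  e2 <- max(abs(as.matrix(solve_hlv(p, c(0.5, 0.5), times, step = 0.6)[, 2:3]) -
                as.matrix(ref[, 2:3])))
  expect_gt(e1 / e2, 8)   # ~16x for a fourth-order method
  expect_lt(e1 / e2, 40)
})

test_that("solver agrees with an adaptive ODE oracle on a coupled case", {
  p <- c(0.6, 24, -0.08, 0.5, 21.5, -0.2)
  times <- seq(0, 36, by = 3)
  mine <- solve_hlv(p, c(0.5, 0.5), times, step = 0.01)
  rhs <- function(t, y, parms)
    list(c(p[1] * y[1] * (1 - y[1] / p[2]) + p[1] * y[1] * (p[3] / (1 + y[1])) * y[2],
           p[4] * y[2] * (1 - y[2] / p[5]) + p[4] * y[2] * (p[6] / (1 + y[2])) * y[1]))
  ora <- deSolve::lsoda(c(0.5, 0.5), times, rhs, NULL, rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(mine$E - ora[, 2])), 1e-5)
  expect_lt(max(abs(mine$S - ora[, 3])), 1e-5)
})

test_that("diverging trajectories raise an error naming the time", {
  expect_error(solve_hlv(c(1, 1e6, 500, 1, 1e6, 500), c(10, 10),
                         seq(0, 36, by = 4), step = 0.01),
               "diverged.*t = ")
})

test_that("trajectory decomposition is exact and sign-consistent", {
  p <- base_theta()
  times <- times16()
  d <- decompose_trajectory(p, c(0.5, 0.5), times, step = 0.05)
  # net = independent + dependent, exactly by construction
  expect_identical(d$net_E, d$independent_E + d$dependent_E)
  expect_identical(d$net_S, d$independent_S + d$dependent_S)
  # mutual antagonism depresses both species at all times
  expect_true(all(d$dependent_E <= 1e-12))
  expect_true(all(d$dependent_S <= 1e-12))
  # no interaction -> dependent components identically zero
  d0 <- decompose_trajectory(c(0.5, 24, 0, 0.4, 21.5, 0), c(0.5, 0.5),
                             times, step = 0.05)
  expect_identical(d0$dependent_E, rep(0, length(times)))
  expect_identical(d0$dependent_S, rep(0, length(times)))
})

test_that("classical growth curves use the documented parameterizations", {
  gl <- growth_params("logistic", K = 23.94, a = 0.29, b = 0.22)
  expect_equal(classical_growth_curve(gl, 1000), 23.94, tolerance = 1e-8)
  gg <- growth_params("gompertz", K = 10, a = 1.3, b = 0.2)
  expect_equal(classical_growth_curve(gg, 0), 10 * exp(-1.3))
  gr <- growth_params("richards", K = 15, a = 2, b = 0.3, m = 1)
  t <- seq(0, 20, by = 2)
  expect_equal(classical_growth_curve(gr, t),
               classical_growth_curve(growth_params("logistic", 15, 2, 0.3), t))
  expect_error(growth_params("richards", K = 15, a = 2, b = 0.3, m = 0),
               "nonzero")
  expect_error(growth_params("richards", K = 15, a = 2, b = 0.3), "requires m")
  expect_error(growth_params("logistic", K = -1, a = 2, b = 0.3), "positive")
})
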