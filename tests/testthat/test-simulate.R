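test_that("heritability calibration solves the variance identity", {
  # scalar check: genetic variance 1 at the reference time, phi = 0,
  # h2 = 0.5 -> innovation SD 1
  curves <- list(A = data.frame(time = c(0, 1), E = c(-1, -1), S = c(-1, -1)),
                 a = data.frame(time = c(0, 1), E = c(1, 1), S = c(1, 1)))
  sad <- calibrate_noise_from_h2(curves, c(0.5, 0.5), 0.5,
                                 sad_params(0, 0, 9, 9, 0),
                                 reference_index = c(1, 1))
  expect_equal(sad$nu_e, 1, tolerance = 1e-12)
  expect_equal(sad$nu_s, 1, tolerance = 1e-12)
  # h2 = 0 keeps the template unchanged
  sad0 <- calibrate_noise_from_h2(curves, c(0.5, 0.5), 0,
                                  sad_params(0.3, 0.2, 9, 8, 0.1))
  expect_equal(sad0$nu_e, 9)
  expect_equal(sad0$nu_s, 8)
  # h2 > 0 with no genetic variance is impossible
  flat <- list(A = curves$A, a = curves$A)
  expect_error(calibrate_noise_from_h2(flat, c(0.5, 0.5), 0.2,
                                       sad_params(0, 0, 1, 1, 0)),
               "nonzero genetic variance")
})

test_that("simulated heritability matches the configured value (round trip)", {
  cfg <- sim_config(n_pairs = 2000, n_markers = 2, causal_marker_A = 1,
                    causal_marker_B = 1, h2 = 0.10,
                    include_monoculture = FALSE)
  ds <- simulate_community(cfg, seed = 77)
  combo <- factor(ds$truth$combination, levels = c("AB", "Ab", "aB", "ab"))
  T <- length(ds$times)
  # reference indices: per-species argmax of the genetic variance of the
  # true mean curves
  th <- ds$truth$theta
  mu <- sapply(rownames(th), function(j) {
    m <- solve_hlv(th[j, ], c(0.5, 0.5), ds$times, 0.05)
    c(m$E, m$S)
  })
  f <- ds$truth$frequencies
  vg <- as.numeric((mu - as.numeric(mu %*% f))^2 %*% f)
  ref_E <- which.max(vg[1:T])
  ref_S <- which.max(vg[(T + 1):(2 * T)]) + T
  h2_emp <- function(col) {
    y <- ds$Y_cc[, col]
    between <- var(ave(y, combo)) * (length(y) - 1) / length(y)
    between / (var(y) * (length(y) - 1) / length(y))
  }
  expect_lt(abs(h2_emp(ref_E) - 0.10), 0.02)
  expect_lt(abs(h2_emp(ref_S) - 0.10), 0.02)
})

test_that("simulation is reproducible and respects the frequency law", {
  cfg <- small_sim_config(h2 = 0.05)
  ds1 <- simulate_community(cfg, seed = 42)
  ds2 <- simulate_community(cfg, seed = 42)
  expect_identical(ds1, ds2)
  ds3 <- simulate_community(cfg, seed = 43)
  expect_false(identical(ds1$Y_cc, ds3$Y_cc))

  # combination counts follow the allele-frequency product law
  big <- sim_config(n_pairs = 2000, n_markers = 2, causal_marker_A = 1,
                    causal_marker_B = 1, h2 = 0, include_monoculture = FALSE)
  dsb <- simulate_community(big, seed = 8)
  counts <- table(factor(dsb$truth$combination,
                         levels = c("AB", "Ab", "aB", "ab")))
  p <- stats::chisq.test(counts, p = rep(0.25, 4))$p.value
  expect_gt(p, 0.001)
})

test_that("with zero heritability the causal locus behaves like a null locus", {
  # distribution of the causal-marker LR matches a non-causal marker's
  # across replicates (monoculture test for speed)
  lr_c <- numeric(40); lr_n <- numeric(40)
  cfg <- sim_config(n_pairs = 45, n_markers = 4, causal_marker_A = 2,
                    causal_marker_B = 2, h2 = 0)
  for (r in 1:40) {
    ds <- simulate_community(cfg, seed = 100 + r)
    for (m in c(2, 4)) {
      asg <- hlvqtl:::marker_classes(ds$genotypes_A[, m], "A")
      if (length(table(asg)) < 2 || any(table(asg) < 2)) next
      tst <- suppressWarnings(
        hlvqtl:::test_locus_mono(ds$Y_mono_A, asg, ds$times, mono_control()))
      if (m == 2) lr_c[r] <- tst$lr else lr_n[r] <- tst$lr
    }
  }
  ks <- suppressWarnings(stats::ks.test(lr_c, lr_n))
  expect_gt(ks$p.value, 0.01)
})

test_that("the power study returns well-formed rates", {
  settings <- data.frame(n = c(30, 30), h2 = c(0, 0.4))
  res <- power_fpr_study(settings, replicates = 8, seed = 5)
  expect_equal(nrow(res), 2)
  expect_equal(res$kind, c("fpr", "power"))
  expect_true(all(res$rate >= 0 & res$rate <= 1))
  expect_true(all(res$ci_lo <= res$rate & res$rate <= res$ci_hi))
  expect_equal(res$threshold, rep(qchisq(0.95, 18), 2), tolerance = 1e-10)
  # a large simulated effect is detected essentially always
  expect_gt(res$rate[2], res$rate[1])
})
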