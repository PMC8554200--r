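test_that("LR statistic arithmetic, clipping and validation", {
  expect_equal(lr_statistic(-100, -100), 0)
  expect_equal(lr_statistic(-100, -90), 20)
  expect_equal(suppressWarnings(lr_statistic(-90, -90 - 1e-8)), 0)
  expect_warning(lr_statistic(-90, -91), "clipping")
  expect_error(lr_statistic(NA, -90), "finite")
  expect_error(lr_statistic(-90, Inf), "finite")
})

test_that("Bonferroni chi-square thresholds match the quantile function", {
  expect_equal(bonferroni_chisq_threshold(1, 0.05, 1), 3.841459,
               tolerance = 1e-6)
  expect_equal(bonferroni_chisq_threshold(1, 1e-6, 18),
               qchisq(1e-6, 18, lower.tail = FALSE))
  expect_equal(bonferroni_chisq_threshold(100, 0.05, 6),
               qchisq(0.0005, 6, lower.tail = FALSE))
  expect_equal(bonferroni_chisq_threshold(1, 1, 3), 0)
  expect_error(bonferroni_chisq_threshold(1, 0.05, 0), "df")
  expect_error(bonferroni_chisq_threshold(0, 0.05, 1), "n_tests")
  expect_error(threshold_spec(alpha = 0), "alpha")
  expect_error(threshold_spec("permutation", n_perm = 10), ">= 20")
})

test_that("the causal locus dominates single- and two-genome scans", {
  cfg <- sim_config(n_pairs = 60, n_markers = 6, causal_marker_A = 3,
                    causal_marker_B = 4, h2 = 0.4)
  ds <- simulate_community(cfg, seed = 5)
  thr <- threshold_spec(alpha = 0.05, n_tests = 1)
  sc <- scan_one_genome(ds$genotypes_A, ds, "coculture", "A",
                        threshold = thr, control = fast_control())
  expect_equal(nrow(sc), 6)
  expect_equal(sc$marker[which.max(sc$lr)], "mA0003")
  expect_true(sc$significant[sc$marker == "mA0003"])

  scm <- scan_one_genome(ds$genotypes_A, ds, "monoculture", "A",
                         threshold = thr, control = fast_control())
  expect_equal(scm$marker[which.max(scm$lr)], "mA0003")
  expect_equal(scm$df[1], 2)

  sc2 <- scan_two_genomes(ds$genotypes_A[, 2:4], ds$genotypes_B[, 3:5], ds,
                          threshold = thr, control = fast_control())
  expect_equal(nrow(sc2), 9)
  top <- sc2[which.max(sc2$lr), ]
  expect_equal(c(top$marker_A, top$marker_B), c("mA0003", "mB0004"))
  expect_equal(sc2$df[1], 18)
})

test_that("monomorphic and undersized markers are skipped with reasons", {
  cfg <- small_sim_config(h2 = 0)
  ds <- simulate_community(cfg, seed = 2)
  ds$genotypes_A[, 1] <- 1                # monomorphic
  ds$genotypes_A[, 2] <- c(1, rep(0, 19)) # singleton class
  sc <- scan_one_genome(ds$genotypes_A[, 1:3], ds, "monoculture", "A",
                        threshold = threshold_spec(alpha = 0.05, n_tests = 1),
                        control = mono_control())
  expect_equal(nrow(sc), 1)
  skipped <- attr(sc, "skipped")
  expect_setequal(skipped$marker, c("mA0001", "mA0002"))
  expect_match(skipped$reason[skipped$marker == "mA0001"], "monomorphic")
  expect_match(skipped$reason[skipped$marker == "mA0002"], "<2")
})

test_that("identical phenotype profiles produce negligible LR", {
  times <- times16()
  mu <- c(solve_hlv(base_theta(), c(0.5, 0.5), times, 0.05)$E,
          solve_hlv(base_theta(), c(0.5, 0.5), times, 0.05)$S)
  set.seed(4)
  Y <- matrix(rep(mu, 16), 16, byrow = TRUE) +
    matrix(rnorm(16 * 32, sd = 0.01), 16)
  asg <- factor(rep(c("A", "a"), each = 8))
  tst <- suppressWarnings(hlvqtl:::test_locus_cc(Y, asg, times, fast_control()))
  expect_lt(tst$lr, qchisq(0.999, tst$df))
})

test_that("subset tests attribute effects to the right parameter block", {
  base <- base_theta()
  thA <- rbind(AB = base, Ab = base, aB = base, ab = base)
  thA[, "alpha_es"] <- c(-0.11, -0.05, -0.11, -0.05)
  thA[, "alpha_se"] <- c(-0.2, -0.2, -0.1, -0.1)
  dA <- make_combo_data(thA, n_per = 15, seed = 2)
  fA <- fit_hlv_model(dA$Y, dA$assignment, dA$times,
                      control = fast_control(polish = "bfgs"))
  tiA <- subset_test(dA$Y, dA$assignment, dA$times, "interaction",
                     control = fast_control(polish = "bfgs"), full_fit = fA)
  tgA <- subset_test(dA$Y, dA$assignment, dA$times, "independent",
                     control = fast_control(polish = "bfgs"), full_fit = fA)
  expect_true(tiA$significant)
  expect_false(tgA$significant)
  expect_gt(tiA$lr, tgA$lr)
  expect_equal(tiA$df, 12)  # (r_e, alpha_es, r_s, alpha_se) x 3 extra sets

  thK <- rbind(AB = base, Ab = base, aB = base, ab = base)
  thK[, "K_e"] <- c(27, 27, 22, 22)
  thK[, "K_s"] <- c(24, 20, 24, 20)
  dK <- make_combo_data(thK, n_per = 15, seed = 3)
  fK <- fit_hlv_model(dK$Y, dK$assignment, dK$times,
                      control = fast_control(polish = "bfgs"))
  tiK <- subset_test(dK$Y, dK$assignment, dK$times, "interaction",
                     control = fast_control(polish = "bfgs"), full_fit = fK)
  tgK <- subset_test(dK$Y, dK$assignment, dK$times, "independent",
                     control = fast_control(polish = "bfgs"), full_fit = fK)
  expect_true(tgK$significant)
  expect_gt(tgK$lr, tiK$lr)

  # identical combinations: both constrained tests are near zero
  th0 <- rbind(AB = base, Ab = base, aB = base, ab = base)
  d0 <- make_combo_data(th0, n_per = 8, seed = 4)
  f0 <- fit_hlv_model(d0$Y, d0$assignment, d0$times, control = fast_control(polish = "bfgs"))
  ti0 <- subset_test(d0$Y, d0$assignment, d0$times, "interaction",
                     control = fast_control(polish = "bfgs"), full_fit = f0)
  expect_lt(ti0$lr, qchisq(0.999, ti0$df))
})

test_that("permutation thresholds are reproducible order statistics", {
  cfg <- small_sim_config(h2 = 0, n_pairs = 24)
  ds <- simulate_community(cfg, seed = 9)
  spec <- threshold_spec("permutation", alpha = 0.05, n_perm = 40)
  c1 <- permutation_threshold(ds$genotypes_A[, 1:3], ds, spec,
                              culture_mode = "monoculture", genome = "A",
                              control = mono_control(), seed = 123)
  c2 <- permutation_threshold(ds$genotypes_A[, 1:3], ds, spec,
                              culture_mode = "monoculture", genome = "A",
                              control = mono_control(), seed = 123)
  expect_identical(as.numeric(c1), as.numeric(c2))
  maxes <- attr(c1, "max_lr")
  expect_length(maxes, 40)
  # order statistic floor((1-alpha) B) + 1 = 39th of 40
  expect_equal(as.numeric(c1), sort(maxes)[39])
  expect_error(
    permutation_threshold(ds$genotypes_A[, 1:3], ds,
                          threshold_spec("permutation", alpha = 0.01,
                                         n_perm = 20),
                          culture_mode = "monoculture", genome = "A",
                          control = mono_control(), seed = 1),
    "too few permutations")
})
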