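#' Likelihood-ratio statistic
#'
#' `LR = 2 (logL1 - logL0)` for nested fits.  Small negative values (within
#' optimizer tolerance) are clipped to zero; larger negative values are
#' clipped with a warning, since they indicate incomplete convergence of
#' the alternative fit.
#'
#' @param loglik_null,loglik_alt Maximized log-likelihoods of the null and
#'   alternative fits.
#' @return The LR statistic (>= 0).
#' @export
lr_statistic <- function(loglik_null, loglik_alt) {
  if (!is.finite(loglik_null) || !is.finite(loglik_alt))
    stop("log-likelihoods must be finite")
  lr <- 2 * (loglik_alt - loglik_null)
  if (lr < -1e-6)
    warning("negative LR (", format(lr), ") beyond tolerance; alternative fit ",
            "may not have converged -- clipping to 0")
  max(lr, 0)
}

#' Significance-threshold specification
#'
#' @param method `"permutation"` (empirical genome-wide max-LR quantile) or
#'   `"bonferroni_chisq"` (chi-square quantile with Bonferroni correction).
#' @param alpha Significance level in (0, 1).  For `bonferroni_chisq` with
#'   `n_tests = 1` this is the per-test level.
#' @param n_perm Number of permutations (>= 20; `permutation` only).
#' @param df Chi-square degrees of freedom; if `NULL` it is taken from the
#'   difference in free parameters of the fits being compared.
#' @param n_tests Number of tests for the Bonferroni correction; if `NULL`
#'   the number of tested units in the scan is used.
#' @return A list of class `threshold_spec`.
#' @export
threshold_spec <- function(method = c("bonferroni_chisq", "permutation"),
                           alpha = 0.05, n_perm = 1000, df = NULL,
                           n_tests = NULL) {
  method <- match.arg(method)
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (method == "permutation" && n_perm < 20)
    stop("permutation count must be >= 20")
  structure(list(method = method, alpha = alpha, n_perm = n_perm,
                 df = df, n_tests = n_tests),
            class = "threshold_spec")
}

#' Bonferroni-corrected chi-square critical value
#'
#' Upper chi-square quantile at level `alpha / n_tests`.  Called with
#' `n_tests = 1`, `alpha` is interpreted as the already-corrected per-test
#' level.
#'
#' @param n_tests Number of tests (>= 1).
#' @param alpha Significance level in (0, 1].
#' @param df Degrees of freedom (>= 1).
#' @return The critical value c with `P(chisq_df >= c) = alpha / n_tests`.
#' @export
bonferroni_chisq_threshold <- function(n_tests, alpha, df) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (!is.finite(df) || df < 1) stop("df must be >= 1")
  qchisq(alpha / n_tests, df = df, lower.tail = FALSE)
}

## ---- single-locus tests --------------------------------------------------

# Null vs genotype-specific fit at one locus of the co-culture data.
# The alternative is warm-started from the null solution, so LR >= 0 holds
# structurally (Nelder-Mead never moves uphill from its start); the null
# is then re-polished from the collapsed alternative solution so that
# incomplete convergence cannot inflate the statistic asymmetrically.
test_locus_cc <- function(Y, assignment, times, control = hlv_fit_control()) {
  fit0 <- fit_hlv_model(Y, assignment, times, mode = "null", control = control)
  fit1 <- fit_hlv_model(Y, assignment, times, mode = "by_combination",
                        control = control, start = fit0)
  fit0b <- fit_hlv_model(Y, assignment, times, mode = "null",
                         control = control, start = fit1)
  if (fit0b$loglik > fit0$loglik) fit0 <- fit0b
  list(lr = lr_statistic(fit0$loglik, fit1$loglik),
       df = fit1$n_free - fit0$n_free, fit0 = fit0, fit1 = fit1)
}

test_locus_mono <- function(Y, assignment, times, control = hlv_fit_control()) {
  fit0 <- fit_mono_model(Y, assignment, times, mode = "null", control = control)
  fit1 <- fit_mono_model(Y, assignment, times, mode = "by_combination",
                         control = control, start = fit0)
  fit0b <- fit_mono_model(Y, assignment, times, mode = "null",
                          control = control, start = fit1)
  if (fit0b$loglik > fit0$loglik) fit0 <- fit0b
  list(lr = lr_statistic(fit0$loglik, fit1$loglik),
       df = fit1$n_free - fit0$n_free, fit0 = fit0, fit1 = fit1)
}

# genotype classes of one marker, coded from the 0/1 haploid alleles
marker_classes <- function(g, genome = c("A", "B")) {
  genome <- match.arg(genome)
  lab <- if (genome == "A") c("a", "A") else c("b", "B")
  factor(ifelse(g == 1, lab[2], lab[1]), levels = lab)
}

flatten_theta <- function(fit) {
  th <- fit$theta
  out <- as.numeric(t(th))
  names(out) <- as.vector(t(outer(rownames(th), colnames(th),
                                  function(a, b) paste(b, a, sep = "_"))))
  out
}

skip_record <- function(marker, reason)
  data.frame(marker = marker, reason = reason, stringsAsFactors = FALSE)

# shared scan driver over a list of (unit id, assignment factor) candidates
scan_driver <- function(units, Y, times, control, tester) {
  rows <- list(); skipped <- list()
  for (u in units) {
    tab <- table(droplevels(u$assignment))
    if (length(tab) < u$min_classes) {
      skipped[[length(skipped) + 1L]] <- skip_record(u$id, "monomorphic")
      next
    }
    if (any(tab < 2)) {
      skipped[[length(skipped) + 1L]] <-
        skip_record(u$id, paste0("class with <2 individuals (",
                                 paste(names(tab)[tab < 2], collapse = ","), ")"))
      next
    }
    tst <- tester(Y, u$assignment, times, control)
    rows[[length(rows) + 1L]] <-
      c(list(id = u$id, lr = tst$lr, df = tst$df), as.list(flatten_theta(tst$fit1)))
  }
  list(rows = rows, skipped = if (length(skipped)) do.call(rbind, skipped)
                              else skip_record(character(), character()))
}

finish_scan <- function(res, threshold, id_cols) {
  if (!length(res$rows)) {
    out <- data.frame()
  } else {
    out <- do.call(rbind, lapply(res$rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  thr <- NA_real_
  if (nrow(out)) {
    df <- out$df[1]
    thr <- threshold$value
    if (is.null(thr)) {
      n_tests <- if (!is.null(threshold$n_tests)) threshold$n_tests else nrow(out)
      dfx <- if (!is.null(threshold$df)) threshold$df else df
      thr <- bonferroni_chisq_threshold(n_tests, threshold$alpha, dfx)
    }
    out$threshold <- thr
    out$significant <- out$lr >= thr
    ord <- c(id_cols, "lr", "df", "threshold", "significant",
             setdiff(names(out), c(id_cols, "lr", "df", "threshold", "significant")))
    out <- out[, ord]
  }
  attr(out, "skipped") <- res$skipped
  class(out) <- c("hlv_scan", class(out))
  out
}

#' Single-genome likelihood-ratio scan
#'
#' Tests every polymorphic marker of one genome for association with the
#' growth trajectories: the shared-curve null fit is compared with a fit in
#' which each genotype class has its own parameter set.  In co-culture mode
#' both species' trajectories are modelled jointly by the coupled system;
#' in monoculture mode the focal species follows its standalone logistic
#' dynamics.
#'
#' @param genotypes Strains x markers 0/1 matrix for the scanned genome
#'   (rownames = strain ids matching the dataset's pairing table).
#' @param dataset A `community_dataset` (see [simulate_community()] /
#'   [read_community_dataset()]).
#' @param culture_mode `"coculture"` or `"monoculture"`.
#' @param genome `"A"` or `"B"`: which genome (species) is scanned.
#' @param threshold A [threshold_spec()].
#' @param control An [hlv_fit_control()].
#' @param seed Seed for the permutation threshold (if used).
#' @return A data frame of class `hlv_scan`, one row per tested marker with
#'   columns `marker`, `lr`, `df`, `threshold`, `significant` and the
#'   flattened per-class estimates; skipped markers (with reasons) are in
#'   `attr(, "skipped")`.
#' @export
scan_one_genome <- function(genotypes, dataset,
                            culture_mode = c("coculture", "monoculture"),
                            genome = c("A", "B"),
                            threshold = threshold_spec(),
                            control = hlv_fit_control(), seed = NULL) {
  culture_mode <- match.arg(culture_mode)
  genome <- match.arg(genome)
  G <- align_genotypes(genotypes, dataset, genome)
  Y <- if (culture_mode == "coculture") coculture_matrix(dataset)
       else monoculture_matrix(dataset, genome)
  times <- dataset$times
  tester <- if (culture_mode == "coculture") test_locus_cc else test_locus_mono
  markers <- colnames(G)
  units <- lapply(seq_along(markers), function(m)
    list(id = markers[m], assignment = marker_classes(G[, m], genome),
         min_classes = 2L))
  if (threshold$method == "permutation") {
    thr <- permutation_threshold(genotypes, dataset, threshold,
                                 culture_mode = culture_mode, genome = genome,
                                 control = control, seed = seed)
    threshold$value <- thr
  }
  res <- scan_driver(units, Y, times, control, tester)
  out <- finish_scan(res, threshold, "id")
  if (nrow(out)) names(out)[names(out) == "id"] <- "marker"
  out
}

#' Two-genome pairwise likelihood-ratio scan
#'
#' For every pair of polymorphic markers (one per genome), forms the four
#' interspecific genotype combinations and compares the shared-curve null
#' fit with the four-combination fit of the coupled co-culture model.
#'
#' @param genotypes_A,genotypes_B Strains x markers 0/1 matrices.
#' @param dataset A `community_dataset`.
#' @param threshold A [threshold_spec()]; the default Bonferroni chi-square
#'   corrects for the number of tested pairs.
#' @param control An [hlv_fit_control()].
#' @return A data frame of class `hlv_scan`, one row per tested marker pair
#'   (`marker_A`, `marker_B`, species A first).
#' @export
scan_two_genomes <- function(genotypes_A, genotypes_B, dataset,
                             threshold = threshold_spec(),
                             control = hlv_fit_control()) {
  GA <- align_genotypes(genotypes_A, dataset, "A")
  GB <- align_genotypes(genotypes_B, dataset, "B")
  Y <- coculture_matrix(dataset)
  times <- dataset$times
  units <- list()
  for (ma in colnames(GA)) for (mb in colnames(GB)) {
    fa <- marker_classes(GA[, ma], "A")
    fb <- marker_classes(GB[, mb], "B")
    units[[length(units) + 1L]] <-
      list(id = paste(ma, mb, sep = ":"),
           assignment = combination_factor(fa, fb), min_classes = 4L)
  }
  res <- scan_driver(units, Y, times, control, test_locus_cc)
  out <- finish_scan(res, threshold, "id")
  if (nrow(out)) {
    sp <- strsplit(out$id, ":", fixed = TRUE)
    out$marker_A <- vapply(sp, `[`, "", 1)
    out$marker_B <- vapply(sp, `[`, "", 2)
    out$id <- NULL
    ord <- c("marker_A", "marker_B",
             setdiff(names(out), c("marker_A", "marker_B")))
    out <- out[, ord]
    class(out) <- c("hlv_scan", "data.frame")
  }
  out
}

#' Interspecific genotype-combination factor
#'
#' Combines the genotype classes of a species-A marker and a species-B
#' marker into the four combinations `AB`, `Ab`, `aB`, `ab`.
#'
#' @param class_A Factor with levels `a`, `A` (or 0/1 alleles).
#' @param class_B Factor with levels `b`, `B` (or 0/1 alleles).
#' @return A factor with levels among `AB`, `Ab`, `aB`, `ab`.
#' @export
combination_factor <- function(class_A, class_B) {
  if (!is.factor(class_A)) class_A <- marker_classes(class_A, "A")
  if (!is.factor(class_B)) class_B <- marker_classes(class_B, "B")
  f <- factor(paste0(as.character(class_A), as.character(class_B)),
              levels = c("AB", "Ab", "aB", "ab"))
  droplevels(f)
}

#' Parameter-subset tests at a significant locus
#'
#' Tests whether a locus acts through the *independent* growth machinery
#' (rates and capacities: `r_e, K_e, r_s, K_s` constrained equal across
#' combinations, interaction scalars free) or through the *interaction*
#' machinery (`r_e, alpha_es, r_s, alpha_se` constrained equal, capacities
#' free).  The constrained fit is compared against the full
#' by-combination fit.
#'
#' @param Y Co-culture phenotype matrix (rows = pairs, columns E block then
#'   S block).
#' @param assignment Genotype-combination factor.
#' @param times Observation times.
#' @param which `"independent"` or `"interaction"`.
#' @param control An [hlv_fit_control()].
#' @param full_fit Optional precomputed full by-combination `hlv_fit`.
#' @param alpha Per-test significance level for the reported chi-square
#'   threshold.
#' @return A list with `lr`, `df`, `threshold`, `significant`, and the two
#'   fits (`fit_constrained`, `fit_full`).
#' @export
subset_test <- function(Y, assignment, times,
                        which = c("independent", "interaction"),
                        control = hlv_fit_control(), full_fit = NULL,
                        alpha = 0.05) {
  which <- match.arg(which)
  share <- if (which == "independent") c("r_e", "K_e", "r_s", "K_s")
           else c("r_e", "alpha_es", "r_s", "alpha_se")
  if (is.null(full_fit))
    full_fit <- fit_hlv_model(Y, assignment, times, mode = "by_combination",
                              control = control)
  fitc <- fit_hlv_model(Y, assignment, times, mode = "by_combination",
                        share = share, control = control, start = full_fit)
  lr <- lr_statistic(fitc$loglik, full_fit$loglik)
  df <- full_fit$n_free - fitc$n_free
  thr <- bonferroni_chisq_threshold(1, alpha, df)
  list(test = which, lr = lr, df = df, threshold = thr,
       significant = lr >= thr, fit_constrained = fitc, fit_full = full_fit)
}

#' Permutation-based genome-wide LR threshold
#'
#' Permutes the individual-to-genotype assignment (whole phenotype
#' trajectories are kept intact, preserving the longitudinal covariance),
#' rescans all markers per permutation, and returns the empirical
#' `(1 - alpha)` quantile of the per-permutation maximum LR, computed as
#' the order statistic `floor((1 - alpha) B) + 1` of the B maxima.
#'
#' @param genotypes Strains x markers 0/1 matrix.
#' @param dataset A `community_dataset`.
#' @param spec A [threshold_spec()] with `method = "permutation"`.
#' @param culture_mode,genome As in [scan_one_genome()].
#' @param control An [hlv_fit_control()].
#' @param seed Integer seed; the same seed gives an identical threshold.
#' @return The critical value c (scalar), with the per-permutation maxima
#'   in `attr(, "max_lr")`.
#' @export
permutation_threshold <- function(genotypes, dataset, spec,
                                  culture_mode = c("coculture", "monoculture"),
                                  genome = c("A", "B"),
                                  control = hlv_fit_control(), seed = NULL) {
  culture_mode <- match.arg(culture_mode)
  genome <- match.arg(genome)
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$method != "permutation") stop("spec$method must be 'permutation'")
  B <- spec$n_perm
  if ((B + 1) * spec$alpha < 1)
    stop("too few permutations (", B, ") for the (1 - ", spec$alpha,
         ") quantile; need at least ", ceiling(1 / spec$alpha) - 1)
  k <- min(floor((1 - spec$alpha) * B) + 1, B)
  G <- align_genotypes(genotypes, dataset, genome)
  Y <- if (culture_mode == "coculture") coculture_matrix(dataset)
       else monoculture_matrix(dataset, genome)
  times <- dataset$times
  tester <- if (culture_mode == "coculture") test_locus_cc else test_locus_mono
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Y)
  max_lr <- numeric(B)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    lrs <- c(0)
    for (m in seq_len(ncol(G))) {
      asg <- marker_classes(G[perm, m], genome)
      tab <- table(asg)
      if (length(tab) < 2 || any(tab < 2)) next
      lrs <- c(lrs, tester(Y, asg, times, control)$lr)
    }
    max_lr[b] <- max(lrs)
  }
  out <- sort(max_lr)[k]
  attr(out, "max_lr") <- max_lr
  out
}
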