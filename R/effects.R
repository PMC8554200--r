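#' Time-varying genetic effect curve of a single locus
#'
#' Half the pointwise difference between the two genotype-class mean
#' curves, the additive effect of substituting one allele for the other in
#' a haploid panel.
#'
#' @param mu_genotype1,mu_genotype2 Numeric vectors: mean curves of the two
#'   genotype classes on a shared time grid.
#' @return Numeric vector `(mu1 - mu2) / 2`.
#' @export
genetic_effect_curve <- function(mu_genotype1, mu_genotype2) {
  if (length(mu_genotype1) != length(mu_genotype2))
    stop("mean curves must share the same time grid")
  (mu_genotype1 - mu_genotype2) / 2
}

#' Partition genotypic value curves into direct, indirect and epistatic effects
#'
#' Orthogonal 2x2 factorial contrasts of the four interspecific genotype
#' combinations at every time point.  For the focal species, the
#' *direct* effect comes from its own genome, the *indirect* effect from
#' the partner genome, and the *epistatic* effect from the cross-genome
#' interaction:
#' \deqn{mean = (\mu_{AB}+\mu_{Ab}+\mu_{aB}+\mu_{ab})/4}
#' \deqn{own = ((\mu_{AB}+\mu_{Ab})-(\mu_{aB}+\mu_{ab}))/4}
#' \deqn{partner = ((\mu_{AB}+\mu_{aB})-(\mu_{Ab}+\mu_{ab}))/4}
#' \deqn{epistatic = (\mu_{AB}-\mu_{Ab}-\mu_{aB}+\mu_{ab})/4}
#' with `own` mapped to direct and `partner` to indirect when the focal
#' species' genome is the first index (species A / genome A), and the
#' reverse for species B.
#'
#' @param mu_AB,mu_Ab,mu_aB,mu_ab Genotypic value curves of the four
#'   combinations on a shared time grid (first index: genome A allele).
#' @param focal_species `"A"` (its own genome is the first index) or `"B"`.
#' @param times Optional time grid (stored in the result).
#' @return A list of class `effect_decomposition` with curves `mean`,
#'   `direct`, `indirect`, `epistatic`.  The reconstruction
#'   `mu_AB = mean + direct + indirect + epistatic` (with signs flipped per
#'   combination) is exact.
#' @export
partition_genotypic_values <- function(mu_AB, mu_Ab, mu_aB, mu_ab,
                                       focal_species = c("A", "B"),
                                       times = NULL) {
  focal_species <- match.arg(focal_species)
  n <- length(mu_AB)
  if (any(c(length(mu_Ab), length(mu_aB), length(mu_ab)) != n))
    stop("the four curves must share the same time grid")
  mean_c <- (mu_AB + mu_Ab + mu_aB + mu_ab) / 4
  own <- ((mu_AB + mu_Ab) - (mu_aB + mu_ab)) / 4
  partner <- ((mu_AB + mu_aB) - (mu_Ab + mu_ab)) / 4
  epi <- (mu_AB - mu_Ab - mu_aB + mu_ab) / 4
  direct <- if (focal_species == "A") own else partner
  indirect <- if (focal_species == "A") partner else own
  structure(list(times = times, focal_species = focal_species,
                 mean = mean_c, direct = direct, indirect = indirect,
                 epistatic = epi),
            class = "effect_decomposition")
}

# signs of (own, partner, epistatic) contrasts per combination
combination_signs <- function() {
  matrix(c( 1,  1,  1,
            1, -1, -1,
           -1,  1, -1,
           -1, -1,  1),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("AB", "Ab", "aB", "ab"),
                         c("own", "partner", "epistatic")))
}

#' Reconstruct a combination's genotypic value curve from an effect partition
#'
#' @param decomposition An `effect_decomposition`.
#' @param combination One of `"AB"`, `"Ab"`, `"aB"`, `"ab"`.
#' @return The reconstructed genotypic value curve (exact).
#' @export
reconstruct_genotypic_value <- function(decomposition, combination) {
  stopifnot(inherits(decomposition, "effect_decomposition"))
  s <- combination_signs()[combination, ]
  own <- if (decomposition$focal_species == "A") decomposition$direct
         else decomposition$indirect
  partner <- if (decomposition$focal_species == "A") decomposition$indirect
             else decomposition$direct
  decomposition$mean + s["own"] * own + s["partner"] * partner +
    s["epistatic"] * decomposition$epistatic
}

#' Time-varying genetic variance explained by each effect component
#'
#' At each time point, the variance over the four genotype combinations
#' (weighted by their frequencies) of the contribution of one contrast.
#' Under equal frequencies the three effect variances are orthogonal and
#' sum exactly to the total genotypic variance.
#'
#' @param decomposition An `effect_decomposition`.
#' @param combination_frequencies Named numeric vector of frequencies for
#'   `AB`, `Ab`, `aB`, `ab`; must be non-negative and sum to 1.
#' @return A data frame with columns `var_direct`, `var_indirect`,
#'   `var_epistatic` (one row per time point), with the brute-force total
#'   genotypic variance in `attr(, "var_total")`.
#' @export
effect_variance_curves <- function(decomposition,
                                   combination_frequencies =
                                     c(AB = .25, Ab = .25, aB = .25, ab = .25)) {
  stopifnot(inherits(decomposition, "effect_decomposition"))
  f <- combination_frequencies[c("AB", "Ab", "aB", "ab")]
  if (any(is.na(f))) stop("frequencies must be named AB, Ab, aB, ab")
  if (any(f < 0)) stop("frequencies must be non-negative")
  if (abs(sum(f) - 1) > 1e-8) stop("frequencies must sum to 1")
  sg <- combination_signs()
  own <- if (decomposition$focal_species == "A") decomposition$direct
         else decomposition$indirect
  partner <- if (decomposition$focal_species == "A") decomposition$indirect
             else decomposition$direct
  comp <- list(own = own, partner = partner, epistatic = decomposition$epistatic)
  # frequency-weighted variance of the signed contribution s_j * effect(t)
  var_of <- function(effect, signs) {
    m1 <- sum(f * signs)
    effect^2 * (sum(f * signs^2) - m1^2)
  }
  var_own <- var_of(comp$own, sg[, "own"])
  var_partner <- var_of(comp$partner, sg[, "partner"])
  var_epi <- var_of(comp$epistatic, sg[, "epistatic"])
  # brute-force total genotypic variance over the four reconstructed values
  g <- vapply(rownames(sg), function(cm)
    reconstruct_genotypic_value(decomposition, cm),
    numeric(length(decomposition$mean)))
  mbar <- as.numeric(g %*% f)
  var_total <- as.numeric((g - mbar)^2 %*% f)
  out <- data.frame(
    var_direct = if (decomposition$focal_species == "A") var_own else var_partner,
    var_indirect = if (decomposition$focal_species == "A") var_partner else var_own,
    var_epistatic = var_epi)
  attr(out, "var_total") <- var_total
  out
}

#' Effect decomposition table for output
#'
#' Flattens an effect partition and its variance curves into the TSV-ready
#' long layout (one row per time point).
#'
#' @param decomposition An `effect_decomposition`.
#' @param combination_frequencies Passed to [effect_variance_curves()].
#' @param species Label written to the `species` column.
#' @return A data frame with columns `time`, `species`, `mean`, `direct`,
#'   `indirect`, `epistatic`, `var_direct`, `var_indirect`, `var_epistatic`.
#' @export
effects_table <- function(decomposition,
                          combination_frequencies =
                            c(AB = .25, Ab = .25, aB = .25, ab = .25),
                          species = decomposition$focal_species) {
  v <- effect_variance_curves(decomposition, combination_frequencies)
  times <- decomposition$times
  if (is.null(times)) times <- seq_along(decomposition$mean)
  data.frame(time = times, species = species,
             mean = decomposition$mean, direct = decomposition$direct,
             indirect = decomposition$indirect,
             epistatic = decomposition$epistatic, v)
}
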