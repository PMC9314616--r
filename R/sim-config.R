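#' Simulation configuration for pedigrees
#'
#' Bundles the parameters of the pedigree generator. Defaults reproduce the
#' study conditions the downstream analyses assume: families are kept only
#' with at least 10 male and 10 female offspring, and female hindwing colour
#' falls on a 1-6 yellow-orange-red scale with marginal category frequencies
#' of about 3% yellow (scores 1-2), 68% orange (3-4) and 29% red (5-6),
#' independent of genotype.
#'
#' Female colour is generated from a standard-normal latent value (mean =
#' `female_genotype_shift` per W-allele count) cut at fixed quantile-matched
#' bin edges so that at shift 0 the six score bins carry probabilities
#' `female_category_probs` split evenly within each colour category.
#'
#' @param allele_freq_W Founder frequency of the W allele (Hardy-Weinberg
#'   draw), in `[0, 1]`.
#' @param families Number of founder families.
#' @param offspring_per_family Either a single count or a list
#'   `list(type = "poisson", lambda = ...)` for Poisson-distributed brood
#'   sizes.
#' @param min_male_offspring,min_female_offspring Family inclusion filter;
#'   families below either minimum are flagged `excluded` (never dropped).
#' @param female_category_probs Length-3 probability vector over
#'   yellow/orange/red female colour categories; must sum to 1.
#' @param female_genotype_shift Latent-mean offset per W allele carried
#'   (default 0: female colour uncoupled from genotype).
#' @param generations Number of generations to simulate (1 = founders + F1).
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(allele_freq_W = 0.5,
                       families = 452L,
                       offspring_per_family = 40L,
                       min_male_offspring = 10L,
                       min_female_offspring = 10L,
                       female_category_probs = c(0.03, 0.68, 0.29),
                       female_genotype_shift = 0,
                       generations = 1L,
                       seed = 1L) {
  check_probability(allele_freq_W, "allele_freq_W")
  check_count(families, "families")
  if (is.numeric(offspring_per_family)) {
    check_count(offspring_per_family, "offspring_per_family")
  } else if (!is.list(offspring_per_family) ||
             !identical(offspring_per_family$type, "poisson") ||
             !is.numeric(offspring_per_family$lambda) ||
             offspring_per_family$lambda <= 0) {
    stop("offspring_per_family must be a count or list(type='poisson', lambda=...)",
         call. = FALSE)
  }
  check_count(min_male_offspring, "min_male_offspring", min = 0L)
  check_count(min_female_offspring, "min_female_offspring", min = 0L)
  if (length(female_category_probs) != 3L ||
      any(female_category_probs < 0) ||
      abs(sum(female_category_probs) - 1) > 1e-8) {
    stop("female_category_probs must be 3 non-negative values summing to 1",
         call. = FALSE)
  }
  check_count(generations, "generations")
  check_count(seed, "seed", min = 0L)
  structure(
    list(
      allele_freq_W = allele_freq_W,
      families = as.integer(families),
      offspring_per_family = offspring_per_family,
      min_male_offspring = as.integer(min_male_offspring),
      min_female_offspring = as.integer(min_female_offspring),
      female_category_probs = female_category_probs,
      female_genotype_shift = female_genotype_shift,
      generations = as.integer(generations),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Latent-scale bin edges for the female 1-6 colour score
#'
#' The three colour categories are split evenly into their two scores, so the
#' six bins carry probabilities `(p_y/2, p_y/2, p_o/2, p_o/2, p_r/2, p_r/2)`;
#' edges are standard-normal quantiles of the cumulative bin probabilities.
#'
#' @param category_probs Length-3 probability vector (yellow, orange, red).
#' @return Numeric vector of 5 interior bin edges on the latent scale.
#' @export
female_bin_edges <- function(category_probs = c(0.03, 0.68, 0.29)) {
  p6 <- rep(category_probs / 2, each = 2)
  stats::qnorm(cumsum(p6)[1:5])
}
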