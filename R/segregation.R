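#' Pearson chi-square goodness-of-fit test
#'
#' Compares observed phenotype counts with model-expected frequencies.
#' Cells with expected probability 0 carry no degrees of freedom; a positive
#' observation in such a cell is a model violation and raises an
#' "impossible observation" error rather than producing a numeric artefact.
#'
#' @param observed Named or unnamed vector of non-negative integer counts.
#' @param expected_probs Probability vector of the same length, summing to 1.
#' @return List of class `chisq_gof`: `statistic`, `df`, `p_value`,
#'   `expected` (counts used).
#' @export
chi_square_gof <- function(observed, expected_probs) {
  if (length(observed) != length(expected_probs)) {
    stop("observed and expected_probs must have equal length", call. = FALSE)
  }
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed must be non-negative integer counts", call. = FALSE)
  }
  if (any(expected_probs < 0) || abs(sum(expected_probs) - 1) > 1e-8) {
    stop("expected_probs must be non-negative and sum to 1", call. = FALSE)
  }
  n <- sum(observed)
  if (n < 1) stop("total observed count must be >= 1", call. = FALSE)
  zero <- expected_probs == 0
  if (any(observed[zero] > 0)) {
    stop("impossible observation: positive count in a cell with expected probability 0",
         call. = FALSE)
  }
  obs <- observed[!zero]
  exp_counts <- n * expected_probs[!zero]
  statistic <- sum((obs - exp_counts)^2 / exp_counts)
  df <- length(obs) - 1L
  p <- if (df == 0L) 1 else stats::pchisq(statistic, df, lower.tail = FALSE)
  structure(list(statistic = statistic, df = df, p_value = p,
                 expected = exp_counts),
            class = "chisq_gof")
}

#' Pooled segregation test across families
#'
#' For each non-excluded family with an assigned cross, male offspring
#' counts are tested against the cross's expected white/yellow frequencies
#' (each offspring an independent draw); per-stratum Pearson statistics and
#' degrees of freedom are summed.
#'
#' @param families Family table with columns `white_males`, `yellow_males`,
#'   `excluded`, and a cross assignment in `cross` (canonical label).
#' @return A `chisq_gof` result for the pooled test.
#' @export
pooled_segregation_test <- function(families) {
  needed <- c("cross", "white_males", "yellow_males", "excluded")
  missing <- setdiff(needed, names(families))
  if (length(missing)) {
    stop("families table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fams <- families[!families$excluded, , drop = FALSE]
  if (any(is.na(fams$cross))) {
    stop("every non-excluded family needs a cross assignment", call. = FALSE)
  }
  stat <- 0
  df <- 0L
  for (i in seq_len(nrow(fams))) {
    probs <- male_phenotype_distribution(fams$cross[i])
    obs <- c(white = fams$white_males[i], yellow = fams$yellow_males[i])
    if (sum(obs) == 0) next
    r <- chi_square_gof(obs, probs)
    stat <- stat + r$statistic
    df <- df + r$df
  }
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p, expected = NULL),
            class = "chisq_gof")
}

# Yellow-male probability under each of the six cross types.
cross_yellow_probs <- function() {
  crosses <- all_cross_types()
  stats::setNames(
    vapply(crosses, function(cr) male_phenotype_distribution(cr)[["yellow"]],
           numeric(1)),
    crosses
  )
}

#' Infer the parental cross from offspring male phenotype counts
#'
#' Binomial log-likelihood of the yellow-male count under each cross type's
#' yellow probability (0 for the three all-white crosses, then 0.25, 0.5, 1).
#' The maximum-likelihood set is returned in full; the three all-white
#' crosses are an exact likelihood tie whenever no yellow offspring is seen,
#' reported as the identifiability class `"all-white"`. A 100% yellow brood
#' identifies `yy x yy`.
#'
#' @param white_males,yellow_males Non-negative male offspring counts,
#'   totalling at least 1.
#' @return List of class `cross_inference`: `log_lik` (named over the six
#'   crosses), `ml_set`, `identifiability_class`.
#' @export
infer_cross_from_offspring <- function(white_males, yellow_males) {
  if (any(c(white_males, yellow_males) < 0) ||
      white_males + yellow_males < 1) {
    stop("need non-negative counts with at least one offspring", call. = FALSE)
  }
  n <- white_males + yellow_males
  k <- yellow_males
  p <- cross_yellow_probs()
  ll <- ifelse(p == 0 & k > 0, -Inf,
        ifelse(p == 1 & k < n, -Inf,
               k * log(ifelse(p == 0, 1, p)) +
                 (n - k) * log(ifelse(p == 1, 1, 1 - p))))
  names(ll) <- names(p)
  best <- max(ll)
  ml <- names(ll)[ll >= best - 1e-9]
  cls <- if (setequal(ml, c("WW x WW", "WW x Wy", "WW x yy"))) {
    "all-white"
  } else if (length(ml) == 1L) {
    ml
  } else {
    paste(sort(ml), collapse = " | ")
  }
  structure(list(log_lik = ll, ml_set = ml, identifiability_class = cls),
            class = "cross_inference")
}

#' Run cross inference over a family table
#'
#' @param families Family table with `white_males` and `yellow_males`
#'   columns; excluded families are carried with `NA` results.
#' @return Data frame `family`, `ml_set` (collapsed with `;`),
#'   `identifiability_class`, `excluded`, plus per-cross log-likelihoods.
#' @export
infer_families <- function(families) {
  crosses <- all_cross_types()
  out <- lapply(seq_len(nrow(families)), function(i) {
    f <- families[i, ]
    if (isTRUE(f$excluded) || f$white_males + f$yellow_males < 1) {
      ll <- stats::setNames(rep(NA_real_, 6L), crosses)
      return(data.frame(family = f$family, ml_set = NA_character_,
                        identifiability_class = NA_character_,
                        excluded = TRUE, t(ll), check.names = FALSE,
                        stringsAsFactors = FALSE))
    }
    r <- infer_cross_from_offspring(f$white_males, f$yellow_males)
    data.frame(family = f$family, ml_set = paste(r$ml_set, collapse = ";"),
               identifiability_class = r$identifiability_class,
               excluded = FALSE, t(r$log_lik), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
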