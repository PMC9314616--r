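#' Shadow-feature importance screening
#'
#' Random-forest feature selection against a permuted-noise reference, in
#' the style of Boruta: each iteration appends a "shadow" copy of every
#' feature with its values independently permuted, fits a seeded random
#' forest, and records for each real feature whether its importance exceeds
#' the maximum shadow importance. After `n_iter` iterations each feature's
#' win count is compared to a fair coin by an exact two-sided binomial test:
#' significantly above 0.5 confirms the feature, significantly below
#' rejects it, anything else stays tentative. Because a pure-noise feature
#' beats the shadow maximum only rarely, the coin-null makes confirmation
#' conservative.
#'
#' @param x Feature matrix or data frame (numeric columns used).
#' @param labels Class labels.
#' @param n_iter Number of shadow iterations (>= 20).
#' @param seed Integer seed; forests and permutations are derived from it.
#' @param num_trees Trees per forest (default 500).
#' @param alpha Two-sided significance level of the binomial decision
#'   (default 0.01).
#' @return List of class `importance_report`: `decisions` (data frame
#'   `feature`, `wins`, `n_iter`, `p_value`, `status`), `importance_history`
#'   (iterations x features), `shadow_max_history`.
#' @export
shadow_feature_selection <- function(x, labels, n_iter = 100L, seed = 1L,
                                     num_trees = 500L, alpha = 0.01) {
  xm <- numeric_feature_matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes", call. = FALSE)
  n_iter <- check_count(n_iter, "n_iter", min = 20L)
  if (all(apply(xm, 2L, stats::sd) == 0)) {
    stop("degenerate feature set: all columns constant", call. = FALSE)
  }
  p <- ncol(xm)
  feats <- colnames(xm)
  if (is.null(feats)) feats <- paste0("V", seq_len(p))

  wins <- integer(p)
  hist_imp <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, feats))
  hist_shadow <- numeric(n_iter)

  for (it in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, it, 23L)
    shadows <- with_seed(it_seed, apply(xm, 2L, sample))
    colnames(shadows) <- paste0("shadow_", feats)
    xx <- as.data.frame(cbind(xm, shadows))
    fit <- ranger::ranger(
      x = xx, y = labels,
      num.trees = num_trees,
      importance = "impurity",
      mtry = floor(sqrt(ncol(xx))),
      num.threads = 1L,
      seed = derive_seed(seed, it, 29L)
    )
    imp <- fit$variable.importance
    shadow_max <- max(imp[paste0("shadow_", feats)])
    real_imp <- imp[feats]
    wins <- wins + as.integer(real_imp > shadow_max)
    hist_imp[it, ] <- real_imp
    hist_shadow[it] <- shadow_max
  }

  p_two <- vapply(wins, function(w) {
    stats::binom.test(w, n_iter, p = 0.5)$p.value
  }, numeric(1))
  status <- ifelse(p_two < alpha & wins > n_iter / 2, "confirmed",
            ifelse(p_two < alpha & wins < n_iter / 2, "rejected",
                   "tentative"))
  structure(
    list(decisions = data.frame(feature = feats, wins = wins,
                                n_iter = n_iter, p_value = p_two,
                                status = status, stringsAsFactors = FALSE),
         importance_history = hist_imp,
         shadow_max_history = hist_shadow),
    class = "importance_report"
  )
}
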