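test_that("chi-square GOF matches hand values and an independent oracle", {
  r <- chi_square_gof(c(75, 25), c(0.75, 0.25))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- chi_square_gof(c(70, 30), c(0.75, 0.25))
  expect_equal(r2$statistic, 4 / 3, tolerance = 1e-12)
  expect_equal(r2$df, 1L)

  # random small tables against the hand Pearson formula and chisq.test
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    probs <- as.numeric(stats::rgamma(k, 2)); probs <- probs / sum(probs)
    obs <- stats::rmultinom(1, sample(20:200, 1), probs)[, 1]
    r3 <- chi_square_gof(obs, probs)
    expect_equal(r3$statistic, oracle_pearson(obs, probs), tolerance = 1e-10)
    ct <- suppressWarnings(stats::chisq.test(obs, p = probs))
    expect_equal(r3$statistic, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(r3$p_value, unname(ct$p.value), tolerance = 1e-10)
  }
})

test_that("a positive count in a zero-expectation cell is a model violation", {
  expect_error(chi_square_gof(c(0, 30), c(1, 0)), "impossible observation")
  # zero-expectation cell with zero observation drops out of the df
  r <- chi_square_gof(c(30, 0, 10), c(0.75, 0, 0.25))
  expect_equal(r$df, 1L)
})

test_that("pooled segregation test sums strata and handles perfect ratios", {
  fam <- data.frame(cross = "Wy x Wy", white_males = 30, yellow_males = 10,
                    excluded = FALSE, stringsAsFactors = FALSE)
  r <- pooled_segregation_test(fam)
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 1L)

  fam2 <- rbind(fam, data.frame(cross = "Wy x yy", white_males = 12,
                                yellow_males = 8, excluded = FALSE))
  r2 <- pooled_segregation_test(fam2)
  expect_equal(r2$df, 2L)
  expect_equal(r2$statistic,
               oracle_pearson(c(30, 10), c(0.75, 0.25)) +
                 oracle_pearson(c(12, 8), c(0.5, 0.5)),
               tolerance = 1e-12)
  expect_error(pooled_segregation_test(
    data.frame(cross = NA, white_males = 1, yellow_males = 1,
               excluded = FALSE)), "cross assignment")
})

test_that("segregation test is calibrated and has power", {
  # type-I: data generated under the assumed model
  set.seed(17)
  p_reject <- mean(vapply(1:400, function(i) {
    g <- mate_pair("Wy", "Wy", 100, seed = 7000 + i)
    obs <- c(sum(g != "yy"), sum(g == "yy"))
    chi_square_gof(obs, c(0.75, 0.25))$p_value < 0.05
  }, logical(1)))
  expect_gt(p_reject, 0.02)
  expect_lt(p_reject, 0.09)

  # power: true white probability 0.6 tested against 0.75
  rej <- mean(vapply(1:100, function(i) {
    w <- stats::rbinom(1, 400, 0.6)
    chi_square_gof(c(w, 400 - w), c(0.75, 0.25))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.95)
})

test_that("cross inference recovers the generating cross", {
  expect_identical(infer_cross_from_offspring(0, 28)$ml_set, "yy x yy")
  expect_identical(infer_cross_from_offspring(75, 25)$ml_set, "Wy x Wy")
  r <- infer_cross_from_offspring(40, 0)
  expect_setequal(r$ml_set, c("WW x WW", "WW x Wy", "WW x yy"))
  expect_identical(r$identifiability_class, "all-white")
  # the three all-white log-likelihoods tie exactly
  ll <- r$log_lik[c("WW x WW", "WW x Wy", "WW x yy")]
  expect_equal(max(ll) - min(ll), 0)
  expect_error(infer_cross_from_offspring(0, 0), "at least one")
})

test_that("recovery rate at 40 male offspring matches the analytic error", {
  # ML boundary between yellow prob 0.25 and 0.5 sits at 14.76/40, so the
  # exact per-cross recovery is 1 - P(Bin(40,.25) >= 15) for Wy x Wy and
  # 1 - P(Bin(40,.5) <= 14) for Wy x yy; simulation must match both.
  sim_recovery <- function(cross, n_rep = 400, seed0 = 0) {
    mean(vapply(seq_len(n_rep), function(i) {
      g <- mate_pair(parse_cross_vec(cross)[1], parse_cross_vec(cross)[2],
                     40, seed = seed0 + i)
      phen <- male_phenotype(g)
      r <- infer_cross_from_offspring(sum(phen == "white"),
                                      sum(phen == "yellow"))
      identical(r$identifiability_class, cross)
    }, logical(1)))
  }
  acc_wywy <- sim_recovery("Wy x Wy", seed0 = 20000)
  exp_wywy <- 1 - stats::pbinom(14, 40, 0.25, lower.tail = FALSE) -
    stats::dbinom(0, 40, 0.25)
  expect_lt(abs(acc_wywy - exp_wywy), 3 * sqrt(exp_wywy * (1 - exp_wywy) / 400))

  acc_wyyy <- sim_recovery("Wy x yy", seed0 = 30000)
  exp_wyyy <- 1 - stats::pbinom(14, 40, 0.5)
  expect_lt(abs(acc_wyyy - exp_wyyy), 3 * sqrt(exp_wyyy * (1 - exp_wyyy) / 400))

  # yy x yy and Wy x yy are never confused when any white offspring is seen
  for (i in 1:200) {
    g <- mate_pair("Wy", "yy", 40, seed = 40000 + i)
    phen <- male_phenotype(g)
    if (any(phen == "white")) {
      r <- infer_cross_from_offspring(sum(phen == "white"),
                                      sum(phen == "yellow"))
      expect_false("yy x yy" %in% r$ml_set)
    }
  }
})

test_that("pedigree back-trace equals brute-force enumeration", {
  set.seed(55)
  for (rep in 1:12) {
    ped <- random_small_pedigree(8L)
    got <- propagate_pedigree_genotypes(ped)
    want <- oracle_pedigree_marginals(ped)
    expect_equal(
      unname(as.matrix(got[, c("p_WW", "p_Wy", "p_yy")])),
      unname(want$marginals[got$id, ]),
      tolerance = 1e-12
    )
  }
})

test_that("back-trace handles worked cases and degenerate inputs", {
  # white male with a yellow son: the father must carry y
  ped <- data.frame(id = c("dad", "mum", "son"),
                    sire = c(NA, NA, "dad"), dam = c(NA, NA, "mum"),
                    sex = c("male", "female", "male"),
                    phenotype = c("white", NA, "yellow"),
                    stringsAsFactors = FALSE)
  m <- propagate_pedigree_genotypes(ped)
  expect_equal(m$p_Wy[m$id == "dad"], 1, tolerance = 1e-12)
  expect_equal(m$p_yy[m$id == "son"], 1, tolerance = 1e-12)

  # isolated founder: marginals are the Hardy-Weinberg prior
  lone <- data.frame(id = "x", sire = NA, dam = NA, sex = "female",
                     phenotype = NA, stringsAsFactors = FALSE)
  m2 <- propagate_pedigree_genotypes(lone, founder_prior_W = 0.3)
  expect_equal(as.numeric(m2[1, c("p_WW", "p_Wy", "p_yy")]),
               c(0.09, 0.42, 0.49), tolerance = 1e-12)

  # genotype contradicting the dominance phenotype is a data error
  bad <- data.frame(id = "y", sire = NA, dam = NA, sex = "male",
                    phenotype = "yellow", genotype = "WW",
                    stringsAsFactors = FALSE)
  expect_error(propagate_pedigree_genotypes(bad), "inconsistent")

  # cyclic parentage is detected
  cyc <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA), sex = "male",
                    phenotype = c("white", "white"),
                    stringsAsFactors = FALSE)
  expect_error(propagate_pedigree_genotypes(cyc), "cyclic")

  # components above the cap refuse to enumerate
  big <- data.frame(id = paste0("i", 1:6),
                    sire = c(NA, NA, "i1", "i1", "i1", "i1"),
                    dam = c(NA, NA, "i2", "i2", "i2", "i2"),
                    sex = "male", phenotype = "white",
                    stringsAsFactors = FALSE)
  expect_error(propagate_pedigree_genotypes(big, cap = 3L), "too large")
})
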