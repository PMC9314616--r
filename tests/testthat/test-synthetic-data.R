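test_that("founder draws honour degenerate and intermediate allele frequencies", {
  expect_true(all(draw_founder_genotypes(1000, 1, seed = 3) == "WW"))
  expect_true(all(draw_founder_genotypes(1000, 0, seed = 3) == "yy"))
  g <- draw_founder_genotypes(10000, 0.5, seed = 1)
  # Wy has probability 0.5 under Hardy-Weinberg at p = 0.5
  frac <- mean(g == "Wy")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_identical(g, draw_founder_genotypes(10000, 0.5, seed = 1))
  expect_error(draw_founder_genotypes(10, 1.5, 1), "p_W")
})

test_that("mating produces Mendelian offspring", {
  expect_true(all(mate_pair("WW", "yy", 20, 5) == "Wy"))
  expect_true(all(mate_pair("yy", "yy", 20, 5) == "yy"))
  g <- mate_pair("Wy", "Wy", 10000, 2)
  p <- c(WW = 0.25, Wy = 0.5, yy = 0.25)
  for (geno in names(p)) {
    expect_lt(abs(mean(g == geno) - p[[geno]]),
              3 * sqrt(p[[geno]] * (1 - p[[geno]]) / 10000))
  }
})

test_that("male phenotypes are deterministic, female marginals match config", {
  cfg <- sim_config()
  expect_identical(assign_phenotype("Wy", "male", cfg), "white")
  expect_identical(assign_phenotype("WW", "male", cfg), "white")
  expect_identical(assign_phenotype("yy", "male", cfg), "yellow")
  # 1e5 female draws at shift 0: category marginals 3/68/29 within 3 sd
  scores <- assign_phenotype(rep("Wy", 1e5), "female", cfg, seed = 9)
  cat3 <- cut(scores, c(0, 2, 4, 6), labels = c("yellow", "orange", "red"))
  p <- c(yellow = 0.03, orange = 0.68, red = 0.29)
  for (k in names(p)) {
    expect_lt(abs(mean(cat3 == k) - p[[k]]),
              3 * sqrt(p[[k]] * (1 - p[[k]]) / 1e5))
  }
  # a positive genotype shift moves W-carriers redward
  cfg2 <- sim_config(female_genotype_shift = 0.8)
  s_ww <- assign_phenotype(rep("WW", 2e4), "female", cfg2, seed = 4)
  s_yy <- assign_phenotype(rep("yy", 2e4), "female", cfg2, seed = 4)
  expect_gt(mean(s_ww), mean(s_yy))
})

test_that("family simulation is deterministic and flags small broods", {
  cfg <- sim_config(families = 10, offspring_per_family = 5, seed = 7)
  r1 <- simulate_families(cfg)
  r2 <- simulate_families(cfg)
  expect_identical(r1, r2)
  # 5 offspring can never satisfy the 10 male + 10 female filter
  expect_true(all(r1$families$excluded))
  expect_true(all(r1$pedigree$excluded[r1$pedigree$generation == 1]))

  cfg2 <- sim_config(families = 60, offspring_per_family = 40, seed = 11)
  r3 <- simulate_families(cfg2)
  yy_fams <- r3$families[r3$families$cross == "yy x yy", ]
  expect_true(all(yy_fams$white_males == 0))
  # family counts agree with the pedigree tabulation
  counts <- family_phenotype_counts(r3$pedigree)
  expect_equal(counts$white_males[match(r3$families$family, counts$family)],
               r3$families$white_males)
})

test_that("multi-generation mode links offspring as next-generation parents", {
  cfg <- sim_config(families = 6, offspring_per_family = 20,
                    generations = 2, seed = 3)
  r <- simulate_families(cfg)
  g2 <- r$pedigree[r$pedigree$generation == 2, ]
  expect_gt(nrow(g2), 0)
  parents <- unique(c(g2$sire, g2$dam))
  expect_true(all(parents %in%
                    r$pedigree$id[r$pedigree$generation == 1]))
})

test_that("specimens are deterministic, bounded, with disjoint ROI masks", {
  app <- appearance_config()
  s1 <- simulate_specimen("Wy", "male", app, seed = 21)
  s2 <- simulate_specimen("Wy", "male", app, seed = 21)
  expect_identical(s1$channels, s2$channels)
  for (ch in names(s1$channels)) {
    expect_true(all(s1$channels[[ch]] >= 0 & s1$channels[[ch]] <= 1))
  }
  expect_true(all(s1$mask %in% 0:4))  # labels partition the image
})

test_that("noise-free specimens reproduce configured means exactly", {
  means <- default_appearance_means()
  means$sd <- 0
  mk <- default_markings(); mk$count <- 0L
  app <- appearance_config(specimen_sd = 0, means = means, markings = mk)
  sp <- simulate_specimen("WW", "male", app, seed = 1)
  for (roi in c("FW", "HW", "TH", "AB")) {
    cm <- roi_colour_means(sp, roi)
    for (ch in c("uv", "sw", "mw", "lw")) {
      cfg_mean <- means$mean[means$genotype == "WW" & means$sex == "male" &
                              means$roi == roi & means$channel == ch]
      expect_equal(unname(cm$means[ch]), cfg_mean, tolerance = 1e-12)
    }
  }
})

test_that("white homozygotes have lower thorax UV than heterozygotes", {
  app <- appearance_config()
  uv <- function(g) {
    vapply(1:50, function(i) {
      sp <- simulate_specimen(g, "male", app, seed = 1000 + i)
      roi_colour_means(sp, "TH")$means[["uv"]]
    }, numeric(1))
  }
  tt <- t.test(uv("WW"), uv("Wy"), alternative = "less")
  expect_lt(tt$p.value, 1e-6)
})

test_that("cohorts have the requested sizes and distinct rasters", {
  co <- generate_cohort(c(WW = 2, Wy = 2, yy = 2), "male", seed = 5)
  expect_length(co$specimens, 6)
  expect_equal(nrow(co$truth), 6)
  co2 <- generate_cohort(c(WW = 37, Wy = 88, yy = 42), "male",
                         appearance_config(image_size = 32L), seed = 5)
  expect_length(co2$specimens, 167)
  hashes <- vapply(co$specimens,
                   function(s) digest_raster(s$channels$uv), character(1))
  expect_equal(anyDuplicated(hashes), 0L)
})

test_that("specimen and pedigree round-trip through disk formats", {
  dir <- withr::local_tempdir()
  sp <- simulate_specimen("yy", "male", seed = 8)
  tp <- file.path(dir, "s.tif"); mp <- file.path(dir, "s_mask.png")
  write_specimen(sp, tp, mp)
  back <- read_specimen(tp, mp)
  for (ch in names(sp$channels)) {
    expect_equal(back$channels[[ch]], sp$channels[[ch]], tolerance = 1e-6)
  }
  expect_identical(back$mask, sp$mask)

  cfg <- sim_config(families = 4, offspring_per_family = 12, seed = 2)
  ped <- simulate_families(cfg)$pedigree
  pp <- file.path(dir, "ped.csv")
  write_pedigree(ped, pp)
  ped2 <- read_pedigree(pp)
  expect_equal(ped2$genotype, ped$genotype)
  expect_equal(ped2$phenotype, ped$phenotype)
})
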