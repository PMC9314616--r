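test_that("reflectance calibration maps the grey standards correctly", {
  expect_equal(calibrate_reflectance(120, 120, 880), 0.07)
  expect_equal(calibrate_reflectance(880, 120, 880), 0.93)
  expect_equal(calibrate_reflectance(500, 120, 880), 0.5)
  # clipping at the physical range
  expect_equal(calibrate_reflectance(-1000, 120, 880), 0)
  expect_equal(calibrate_reflectance(1e5, 120, 880), 1)
  expect_error(calibrate_reflectance(1, 5, 5), "must exceed")
})

test_that("ROI colour means equal a naive pixel loop", {
  sp <- simulate_specimen("Wy", "male", seed = 14)
  for (roi in c("FW", "AB")) {
    cm <- roi_colour_means(sp, roi)
    code <- c(FW = 1L, HW = 2L, TH = 3L, AB = 4L)[[roi]]
    for (ch in c("uv", "lw")) {
      acc <- 0; npx <- 0L
      img <- sp$channels[[ch]]
      for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
        if (sp$mask[i, j] == code) { acc <- acc + img[i, j]; npx <- npx + 1L }
      }
      expect_equal(unname(cm$means[ch]), acc / npx, tolerance = 1e-12)
      expect_equal(cm$area, npx)
    }
  }
})

test_that("granularity band scales form the expected geometric sequence", {
  b <- granularity_bands()
  expect_length(b, 12)
  expect_equal(b[1:3], c(2, 2.828, 3.999), tolerance = 1e-3)
  expect_equal(b[12], 2 * 1.414^11, tolerance = 1e-12)
  expect_true(all(b <= 100))
  expect_equal(granularity_bands(2, 4, 1.414), c(2, 2 * 1.414, 2 * 1.414^2),
               tolerance = 1e-12)
  expect_length(granularity_bands(2, 1, 1.414), 0)
})

test_that("a period-16 grating peaks in the band nearest 16 px", {
  img <- matrix(rep(rep(c(1, 0), each = 8), length.out = 128 * 128),
                128, 128, byrow = TRUE)
  gs <- suppressWarnings(granularity_spectrum(img))
  peak_scale <- gs$scales[which.max(gs$energy)]
  expect_equal(which.min(abs(gs$scales - 16)),
               which.max(gs$energy))
  expect_lt(abs(peak_scale - 16), 1)
})

test_that("constant images carry zero energy in every band", {
  gs <- suppressWarnings(granularity_spectrum(matrix(0.7, 64, 64)))
  expect_equal(max(abs(gs$energy)), 0)
})

test_that("band energies match the spatial-domain convolution oracle", {
  set.seed(23)
  img <- matrix(stats::rnorm(32 * 32), 32, 32)
  bands <- granularity_bands(2, 16, 1.414)
  got <- granularity_spectrum(img, bands = bands)$energy
  want <- vapply(bands, function(s) oracle_band_energy(img, s), numeric(1))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("band energies are mean-invariant and scale linearly", {
  set.seed(6)
  img <- matrix(stats::rnorm(48 * 48), 48, 48)
  e <- suppressWarnings(granularity_spectrum(img)$energy)
  e_shift <- suppressWarnings(granularity_spectrum(img + 3)$energy)
  e_scaled <- suppressWarnings(granularity_spectrum(img * 2.5)$energy)
  expect_equal(e, e_shift, tolerance = 1e-12)
  expect_equal(e_scaled, 2.5 * e, tolerance = 1e-10)
  # diversity and marking size are scale-free
  gs1 <- suppressWarnings(granularity_spectrum(img))
  gs2 <- suppressWarnings(granularity_spectrum(img * 2.5))
  p1 <- pattern_summaries(gs1); p2 <- pattern_summaries(gs2)
  expect_equal(p1$diversity, p2$diversity, tolerance = 1e-10)
  expect_equal(p1$marking_size, p2$marking_size)
})

test_that("pattern summaries follow their definitions", {
  gs <- structure(list(scales = c(2, 4, 8, 16), energy = c(0, 0, 5, 0)),
                  class = "granularity_spectrum")
  p <- pattern_summaries(gs)
  expect_equal(p$dominance, 5)
  expect_equal(p$diversity, 1)
  expect_equal(p$marking_size, 8)

  gs2 <- structure(list(scales = granularity_bands(),
                        energy = rep(2, 12)),
                   class = "granularity_spectrum")
  p2 <- pattern_summaries(gs2)
  expect_equal(p2$diversity, 1 / 12)
  expect_match(paste(p2$flags, collapse = " "), "tie")
  expect_equal(p2$marking_size, 2)  # tie broken toward the smallest scale

  gs3 <- structure(list(scales = c(2, 4), energy = c(1, 3)),
                   class = "granularity_spectrum")
  p3 <- pattern_summaries(gs3)
  expect_equal(p3$dominance, 3)
  expect_equal(p3$diversity, 0.75)
  expect_equal(p3$marking_size, 4)
  expect_equal(p3$pattern_contrast, sqrt(10))

  gs0 <- structure(list(scales = c(2, 4), energy = c(0, 0)),
                   class = "granularity_spectrum")
  p0 <- pattern_summaries(gs0)
  expect_equal(p0$diversity, 0)
  expect_match(paste(p0$flags, collapse = " "), "all-zero")
})

test_that("luminance histograms bin the dynamic range correctly", {
  sp <- simulate_specimen("WW", "male", seed = 2)
  # force extremes
  sp$channels$lw[sp$mask == 2L] <- 0
  h0 <- luminance_band_histogram(sp, "HW")
  expect_equal(h0[1], 1)
  sp$channels$lw[sp$mask == 2L] <- 1
  h1 <- luminance_band_histogram(sp, "HW")
  expect_equal(h1[20], 1)
  # uniform pixels spread roughly evenly
  set.seed(3)
  sp$channels$lw[sp$mask == 2L] <- stats::runif(sum(sp$mask == 2L))
  h <- luminance_band_histogram(sp, "HW")
  expect_equal(sum(h), 1, tolerance = 1e-12)
  n <- sum(sp$mask == 2L)
  # multinomial GOF against the uniform 1/20 expectation
  gof <- chi_square_gof(round(h * n), rep(0.05, 20))
  expect_gt(gof$p_value, 0.001)
})

test_that("allometric ratios are the named quotients", {
  areas <- c(FW = 200, HW = 100, TH = 50, AB = 100)
  r <- allometric_ratios(areas)
  expect_equal(r, c(FW_AB = 2, FW_TH = 4, FW_HW = 2, TH_AB = 0.5))
  expect_error(allometric_ratios(c(FW = 0, HW = 1, TH = 1, AB = 1)),
               "zero-area")
})

test_that("feature tables have the fixed schema and are deterministic", {
  co <- generate_cohort(c(WW = 2, Wy = 2, yy = 2), "male", seed = 9)
  ft <- build_feature_table(co)
  expect_equal(nrow(ft), 6)
  # 4 meta columns + 4 ROIs x (area + 4 channels + 4 pattern) + 4 ratios
  expect_equal(ncol(ft), 4 + 4 * 9 + 4)
  ft2 <- build_feature_table(co)
  expect_identical(ft, ft2)
  ftl <- build_feature_table(co, include_luminance = TRUE)
  expect_equal(ncol(ftl), 4 + 4 * 9 + 4 + 4 * 20)
})

test_that("correlation filtering drops duplicates and constants, keeps noise", {
  set.seed(12)
  tab <- data.frame(a = stats::rnorm(60), b = stats::rnorm(60),
                    c = stats::rnorm(60))
  tab$dup <- tab$a
  tab$const <- 1
  r <- drop_correlated_features(tab, threshold = 0.9)
  expect_true(xor("a" %in% r$retained, "dup" %in% r$retained))
  expect_false("const" %in% r$retained)
  expect_match(r$dropped$reason[r$dropped$feature == "const"], "zero variance")
  expect_true(all(c("b", "c") %in% r$retained))
  # deterministic
  r2 <- drop_correlated_features(tab, threshold = 0.9)
  expect_identical(r$retained, r2$retained)
})
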