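# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: enumeration instead of recursion, direct
# DFT matrices and spatial convolution instead of fft-multiplication, and
# hand-written closed forms.

GENO3 <- c("WW", "Wy", "yy")

# Punnett enumeration from explicit gamete lists (no probability algebra).
oracle_offspring_distribution <- function(g1, g2) {
  gametes <- function(g) strsplit(g, "")[[1]]
  combos <- expand.grid(a = gametes(g1), b = gametes(g2),
                        stringsAsFactors = FALSE)
  geno <- apply(combos, 1, function(r) {
    paste(sort(c(r[["a"]], r[["b"]])), collapse = "")
  })
  geno[geno == "yW"] <- "Wy"
  tab <- table(factor(geno, GENO3))
  stats::setNames(as.numeric(tab) / sum(tab), GENO3)
}

# Hand Pearson statistic.
oracle_pearson <- function(observed, probs) {
  n <- sum(observed)
  keep <- probs > 0
  e <- n * probs[keep]
  sum((observed[keep] - e)^2 / e)
}

# Brute-force pedigree genotype marginals: enumerate every joint genotype
# assignment with expand.grid and sum joint probabilities directly.
oracle_pedigree_marginals <- function(ped, prior_W = 0.5) {
  n <- nrow(ped)
  if (!"genotype" %in% names(ped)) ped$genotype <- NA_character_
  prior <- c(WW = prior_W^2, Wy = 2 * prior_W * (1 - prior_W),
             yy = (1 - prior_W)^2)
  transmit_y <- c(WW = 0, Wy = 0.5, yy = 1)  # P(parent passes y)
  trans_prob <- function(gs, gd, gc) {
    py_s <- transmit_y[gs]; py_d <- transmit_y[gd]
    switch(gc,
           WW = (1 - py_s) * (1 - py_d),
           Wy = (1 - py_s) * py_d + py_s * (1 - py_d),
           yy = py_s * py_d)
  }
  grid <- do.call(expand.grid,
                  c(rep(list(GENO3), n), stringsAsFactors = FALSE))
  idx <- stats::setNames(seq_len(n), ped$id)
  marg <- matrix(0, n, 3, dimnames = list(ped$id, GENO3))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    g <- as.character(grid[r, ])
    w <- 1
    for (i in seq_len(n)) {
      has_s <- !is.na(ped$sire[i]); has_d <- !is.na(ped$dam[i])
      w <- w * if (has_s && has_d) {
        trans_prob(g[idx[[ped$sire[i]]]], g[idx[[ped$dam[i]]]], g[i])
      } else if (!has_s && !has_d) {
        prior[[g[i]]]
      } else {
        known <- if (has_s) g[idx[[ped$sire[i]]]] else g[idx[[ped$dam[i]]]]
        sum(vapply(GENO3, function(gm) {
          prior[[gm]] * trans_prob(known, gm, g[i])
        }, numeric(1)))
      }
      if (ped$sex[i] == "male" && !is.na(ped$phenotype[i])) {
        white <- g[i] %in% c("WW", "Wy")
        if ((ped$phenotype[i] == "white") != white) w <- 0
      }
      if (!is.na(ped$genotype[i]) && ped$genotype[i] != g[i]) w <- 0
      if (w == 0) break
    }
    if (w > 0) {
      total <- total + w
      for (i in seq_len(n)) marg[i, g[i]] <- marg[i, g[i]] + w
    }
  }
  list(marginals = marg / total, total = total)
}

# Random small pedigree: founders plus a few offspring, male phenotypes
# observed via dominance, occasional recorded genotypes.
random_small_pedigree <- function(n_max = 8L) {
  n_founder <- sample(2:4, 1)
  ids <- paste0("I", seq_len(n_founder))
  ped <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                    sex = sample(c("male", "female"), n_founder, TRUE),
                    genotype = sample(GENO3, n_founder, TRUE),
                    stringsAsFactors = FALSE)
  # force at least one male-female founder pair
  ped$sex[1] <- "male"; ped$sex[2] <- "female"
  while (nrow(ped) < n_max && stats::runif(1) < 0.8) {
    sires <- ped$id[ped$sex == "male"]
    dams <- ped$id[ped$sex == "female"]
    s <- sample(sires, 1); d <- sample(dams, 1)
    gs <- ped$genotype[ped$id == s]; gd <- ped$genotype[ped$id == d]
    probs <- cryptomorph::offspring_genotype_distribution(c(gs, gd))
    gc <- sample(GENO3, 1, prob = probs)
    ped <- rbind(ped, data.frame(
      id = paste0("I", nrow(ped) + 1), sire = s, dam = d,
      sex = sample(c("male", "female"), 1), genotype = gc,
      stringsAsFactors = FALSE))
  }
  ped$phenotype <- NA_character_
  m <- ped$sex == "male"
  ped$phenotype[m] <- cryptomorph::male_phenotype(ped$genotype[m])
  # hide most true genotypes; keep a couple observed at random
  observed <- stats::runif(nrow(ped)) < 0.2
  ped$genotype[!observed] <- NA_character_
  ped
}

# --- spatial-domain granularity oracle --------------------------------------

# Raised-cosine radial response, written independently of the package.
oracle_band_H <- function(nr, nc, scale, factor) {
  H <- matrix(0, nr, nc)
  for (u in 0:(nr - 1)) {
    fu <- min(u, nr - u) / nr
    for (v in 0:(nc - 1)) {
      fv <- min(v, nc - v) / nc
      r <- sqrt(fu^2 + fv^2)
      if (r > 0) {
        t <- log((1 / r) / scale) / log(factor)
        if (abs(t) <= 0.5) H[u + 1, v + 1] <- cos(pi * t)^2
      }
    }
  }
  H
}

# Spatial kernel by explicit inverse DFT (complex matrix products, no fft).
oracle_kernel <- function(H) {
  nr <- nrow(H); nc <- ncol(H)
  Wr <- exp(2i * pi * outer(0:(nr - 1), 0:(nr - 1)) / nr)
  Wc <- exp(2i * pi * outer(0:(nc - 1), 0:(nc - 1)) / nc)
  Re(Wr %*% H %*% t(Wc)) / (nr * nc)
}

# Circular spatial convolution by explicit shifting.
oracle_circular_convolve <- function(img, ker) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (a in 0:(nr - 1)) {
    ridx <- ((seq_len(nr) - 1 - a) %% nr) + 1
    shifted_rows <- img[ridx, , drop = FALSE]
    for (b in 0:(nc - 1)) {
      kab <- ker[a + 1, b + 1]
      if (kab == 0) next
      cidx <- ((seq_len(nc) - 1 - b) %% nc) + 1
      out <- out + kab * shifted_rows[, cidx, drop = FALSE]
    }
  }
  out
}

oracle_band_energy <- function(img, scale, factor = 1.414) {
  H <- oracle_band_H(nrow(img), ncol(img), scale, factor)
  ker <- oracle_kernel(H)
  filt <- oracle_circular_convolve(img, ker)
  stats::sd(filt)
}

parse_cross_vec <- function(cr) strsplit(cr, " x ", fixed = TRUE)[[1]]

# Cheap raster fingerprint for distinctness checks.
digest_raster <- function(m) {
  paste(format(c(sum(m), sum(m^2), m[1, 1], m[nrow(m), ncol(m)]),
               digits = 15), collapse = "|")
}

# Closed-form Fisher discriminant direction for two classes.
oracle_fisher_direction <- function(x, labels) {
  cls <- sort(unique(labels))
  x1 <- x[labels == cls[1], , drop = FALSE]
  x2 <- x[labels == cls[2], , drop = FALSE]
  s1 <- crossprod(scale(x1, scale = FALSE))
  s2 <- crossprod(scale(x2, scale = FALSE))
  Sw <- (s1 + s2) / (nrow(x) - 2)
  solve(Sw, colMeans(x1) - colMeans(x2))
}
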