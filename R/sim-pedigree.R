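#' Draw founder genotypes under Hardy-Weinberg proportions
#'
#' @param n Number of founders.
#' @param p_W Population frequency of the W allele.
#' @param seed Integer seed.
#' @return Character vector of genotypes with probabilities
#'   `p_W^2`, `2 p_W (1 - p_W)`, `(1 - p_W)^2`.
#' @export
draw_founder_genotypes <- function(n, p_W, seed) {
  n <- check_count(n, "n")
  check_probability(p_W, "p_W")
  probs <- c(p_W^2, 2 * p_W * (1 - p_W), (1 - p_W)^2)
  with_seed(seed, sample(GENOTYPES, n, replace = TRUE, prob = probs))
}

#' Mate two parents and draw offspring genotypes
#'
#' Each offspring receives one uniformly drawn allele from each parent
#' (Mendelian transmission).
#'
#' @param g1,g2 Parent genotypes.
#' @param n_offspring Brood size.
#' @param seed Integer seed.
#' @return Character vector of offspring genotypes.
#' @export
mate_pair <- function(g1, g2, n_offspring, seed) {
  g1 <- as_genotype(g1)
  g2 <- as_genotype(g2)
  n <- check_count(n_offspring, "n_offspring")
  with_seed(seed, {
    a1 <- stats::rbinom(n, 1L, gamete_p_W(g1))  # 1 = W transmitted
    a2 <- stats::rbinom(n, 1L, gamete_p_W(g2))
    GENOTYPES[3L - (a1 + a2)]
  })
}

#' Assign a phenotype to an individual
#'
#' Males are deterministic under dominance: `WW`/`Wy` are white, `yy` yellow.
#' Females draw a latent normal value with mean
#' `female_genotype_shift * (number of W alleles)` and are binned to the 1-6
#' colour score at the fixed edges of [female_bin_edges()], so at shift 0 the
#' category marginals equal `cfg$female_category_probs` whatever the genotype.
#'
#' @param g Genotype.
#' @param sex `"male"` or `"female"`.
#' @param cfg A [sim_config()].
#' @param seed Integer seed (used for females only).
#' @return Male: `"white"`/`"yellow"`; female: integer score 1-6.
#' @export
assign_phenotype <- function(g, sex, cfg = sim_config(), seed = 1L) {
  g <- as_genotype(g)
  sex <- match.arg(sex, c("male", "female"))
  if (sex == "male") return(male_phenotype(g))
  edges <- female_bin_edges(cfg$female_category_probs)
  shift <- cfg$female_genotype_shift * W_DOSE[g]
  z <- with_seed(seed, stats::rnorm(length(g), mean = shift, sd = 1))
  findInterval(z, edges) + 1L
}

draw_brood_size <- function(spec, seed) {
  if (is.numeric(spec)) return(as.integer(spec))
  max(1L, with_seed(seed, stats::rpois(1L, spec$lambda)))
}

#' Simulate a multi-generation pedigree of families
#'
#' Founder pairs are drawn under Hardy-Weinberg proportions and mated; each
#' offspring gets a sex (fair coin) and a phenotype via [assign_phenotype()].
#' Families with fewer than `min_male_offspring` males or
#' `min_female_offspring` females are flagged `excluded = TRUE` but retained,
#' so filter effects stay observable. With `generations > 1`, parents of the
#' next generation are sampled from offspring of distinct previous-generation
#' families, linking the pedigree for back-trace.
#'
#' @param cfg A [sim_config()].
#' @return List with `pedigree` (one row per individual: `id`, `family`,
#'   `sire`, `dam`, `generation`, `sex`, `genotype`, `phenotype`, `excluded`)
#'   and `families` (one row per brood with parent genotypes, the true cross,
#'   male phenotype counts, female score counts and the exclusion flag).
#' @export
simulate_families <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  ped <- list()
  fam <- list()
  next_id <- 1L
  fam_id <- 0L

  # generation-0 founder pool
  n_founders <- 2L * cfg$families
  fg <- draw_founder_genotypes(n_founders, cfg$allele_freq_W,
                               derive_seed(cfg$seed, 0L, 1L))
  founders <- data.frame(
    id = sprintf("G0_%05d", seq_len(n_founders)),
    family = NA_character_,
    sire = NA_character_,
    dam = NA_character_,
    generation = 0L,
    sex = rep(c("male", "female"), cfg$families),
    genotype = fg,
    phenotype = NA_character_,
    excluded = FALSE,
    stringsAsFactors = FALSE
  )
  founders$phenotype[founders$sex == "male"] <-
    male_phenotype(founders$genotype[founders$sex == "male"])
  fidx <- which(founders$sex == "female")
  founders$phenotype[fidx] <- as.character(assign_phenotype(
    founders$genotype[fidx], "female", cfg, derive_seed(cfg$seed, 0L, 2L)))
  ped[[1]] <- founders

  sires <- founders$id[founders$sex == "male"]
  dams <- founders$id[founders$sex == "female"]
  geno_of <- stats::setNames(founders$genotype, founders$id)

  for (gen in seq_len(cfg$generations)) {
    gen_offspring <- list()
    for (k in seq_along(sires)) {
      fam_id <- fam_id + 1L
      s <- sires[k]; d <- dams[k]
      nb <- draw_brood_size(cfg$offspring_per_family,
                            derive_seed(cfg$seed, fam_id, 3L))
      og <- mate_pair(geno_of[[s]], geno_of[[d]], nb,
                      derive_seed(cfg$seed, fam_id, 4L))
      sex <- with_seed(derive_seed(cfg$seed, fam_id, 5L),
                       sample(c("male", "female"), nb, replace = TRUE))
      phen <- character(nb)
      m <- sex == "male"
      phen[m] <- male_phenotype(og[m])
      if (any(!m)) {
        phen[!m] <- as.character(assign_phenotype(
          og[!m], "female", cfg, derive_seed(cfg$seed, fam_id, 6L)))
      }
      excl <- sum(m) < cfg$min_male_offspring ||
        sum(!m) < cfg$min_female_offspring
      ids <- sprintf("G%d_%05d", gen, next_id:(next_id + nb - 1L))
      next_id <- next_id + nb
      off <- data.frame(
        id = ids, family = sprintf("F%05d", fam_id), sire = s, dam = d,
        generation = gen, sex = sex, genotype = og, phenotype = phen,
        excluded = excl, stringsAsFactors = FALSE
      )
      gen_offspring[[k]] <- off
      geno_of[ids] <- og

      fscore <- as.integer(phen[!m])
      fam[[fam_id]] <- data.frame(
        family = sprintf("F%05d", fam_id), sire = s, dam = d,
        generation = gen,
        sire_genotype = geno_of[[s]], dam_genotype = geno_of[[d]],
        cross = cross_type(geno_of[[s]], geno_of[[d]]),
        n_male = sum(m), n_female = sum(!m),
        white_males = sum(phen[m] == "white"),
        yellow_males = sum(phen[m] == "yellow"),
        f1 = sum(fscore == 1L), f2 = sum(fscore == 2L),
        f3 = sum(fscore == 3L), f4 = sum(fscore == 4L),
        f5 = sum(fscore == 5L), f6 = sum(fscore == 6L),
        excluded = excl, stringsAsFactors = FALSE
      )
    }
    gen_offspring <- do.call(rbind, gen_offspring)
    ped[[gen + 1L]] <- gen_offspring

    if (gen < cfg$generations) {
      # pair next generation: one male and one female from distinct families
      males <- gen_offspring[gen_offspring$sex == "male", ]
      females <- gen_offspring[gen_offspring$sex == "female", ]
      n_pairs <- cfg$families
      pick <- with_seed(derive_seed(cfg$seed, gen, 7L), {
        ms <- males[sample(nrow(males), n_pairs, replace = nrow(males) < n_pairs), ]
        fs <- females[sample(nrow(females), n_pairs, replace = nrow(females) < n_pairs), ]
        same <- ms$family == fs$family
        tries <- 0L
        while (any(same) && tries < 20L) {
          fs[same, ] <- females[sample(nrow(females), sum(same), replace = TRUE), ]
          same <- ms$family == fs$family
          tries <- tries + 1L
        }
        list(ms = ms, fs = fs)
      })
      sires <- pick$ms$id
      dams <- pick$fs$id
    }
  }

  list(pedigree = do.call(rbind, ped), families = do.call(rbind, fam))
}

#' Tabulate offspring phenotype counts per family from a pedigree
#'
#' @param pedigree Pedigree data frame as produced by [simulate_families()].
#' @return One row per family with male white/yellow counts and female score
#'   counts.
#' @export
family_phenotype_counts <- function(pedigree) {
  off <- pedigree[!is.na(pedigree$family), , drop = FALSE]
  split_fam <- split(off, off$family)
  out <- lapply(split_fam, function(f) {
    m <- f$sex == "male"
    fscore <- suppressWarnings(as.integer(f$phenotype[!m]))
    data.frame(
      family = f$family[1], sire = f$sire[1], dam = f$dam[1],
      n_male = sum(m), n_female = sum(!m),
      white_males = sum(f$phenotype[m] == "white"),
      yellow_males = sum(f$phenotype[m] == "yellow"),
      f1 = sum(fscore == 1L, na.rm = TRUE), f2 = sum(fscore == 2L, na.rm = TRUE),
      f3 = sum(fscore == 3L, na.rm = TRUE), f4 = sum(fscore == 4L, na.rm = TRUE),
      f5 = sum(fscore == 5L, na.rm = TRUE), f6 = sum(fscore == 6L, na.rm = TRUE),
      excluded = f$excluded[1], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write / read a pedigree CSV
#'
#' Column layout: `id, family, sire, dam, generation, sex, genotype,
#' phenotype, excluded`.
#'
#' @param pedigree Pedigree data frame.
#' @param path File path.
#' @return `read_pedigree` returns the pedigree data frame.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(pedigree, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path, call. = FALSE)
  ped <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(phenotype = "character"))
  needed <- c("id", "family", "sire", "dam", "generation", "sex",
              "genotype", "phenotype", "excluded")
  missing <- setdiff(needed, names(ped))
  if (length(missing)) {
    stop("pedigree CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ped
}
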