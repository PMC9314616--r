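#' Back-trace genotype probabilities through a pedigree
#'
#' Exact posterior genotype marginals per individual, obtained by summing
#' the joint probability of every genotype configuration of each connected
#' pedigree component. The joint factorises over the pedigree: founders get
#' Hardy-Weinberg prior probabilities at allele frequency `founder_prior_W`,
#' non-founders a Mendelian transmission probability given their parents,
#' and every male contributes a dominance-phenotype likelihood (white
#' excludes `yy`, yellow forces `yy`). Female phenotypes are treated as
#' uninformative for the locus. Known genotypes in the `genotype` column are
#' conditioned on as observations (set the column to `NA` to infer them).
#'
#' The enumeration prunes zero-probability branches but is exponential in
#' component size, so components larger than `cap` raise an explicit error;
#' split such pedigrees before calling.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam`, `sex`,
#'   `phenotype` (male `"white"`/`"yellow"` or `NA`), optionally `genotype`
#'   (observed genotype or `NA`).
#' @param founder_prior_W Founder W-allele frequency for the Hardy-Weinberg
#'   prior.
#' @param cap Maximum individuals per connected component (default 12).
#' @return Data frame `id`, `p_WW`, `p_Wy`, `p_yy`, `component`; attribute
#'   `component_prob` holds each component's total data probability.
#'   A component whose observations are jointly impossible under the model
#'   raises an inconsistency error.
#' @export
propagate_pedigree_genotypes <- function(pedigree, founder_prior_W = 0.5,
                                         cap = 12L) {
  check_probability(founder_prior_W, "founder_prior_W")
  needed <- c("id", "sire", "dam", "sex", "phenotype")
  missing <- setdiff(needed, names(pedigree))
  if (length(missing)) {
    stop("pedigree missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ped <- pedigree
  ped$sire[ped$sire %in% c("", "NA")] <- NA
  ped$dam[ped$dam %in% c("", "NA")] <- NA
  if (anyDuplicated(ped$id)) stop("duplicate individual ids", call. = FALSE)
  if (!"genotype" %in% names(ped)) ped$genotype <- NA_character_

  # referenced parents must exist
  parents <- stats::na.omit(unique(c(ped$sire, ped$dam)))
  unknown <- setdiff(parents, ped$id)
  if (length(unknown)) {
    stop("parent id(s) not in pedigree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  # observed-genotype vs male-phenotype consistency
  obs <- !is.na(ped$genotype)
  if (any(obs)) {
    ped$genotype[obs] <- as_genotype(ped$genotype[obs])
    midx <- which(obs & ped$sex == "male" & !is.na(ped$phenotype))
    bad <- midx[male_phenotype(ped$genotype[midx]) != ped$phenotype[midx]]
    if (length(bad)) {
      stop("inconsistent pedigree: recorded genotype contradicts male phenotype for ",
           paste(ped$id[bad], collapse = ", "), call. = FALSE)
    }
  }

  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  sire_i <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  dam_i <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])

  # topological order (children after parents); failure means a cycle
  ord <- integer(0)
  placed <- logical(n)
  repeat {
    ready <- which(!placed & vapply(seq_len(n), function(i) {
      !placed[i] &&
        (is.na(sire_i[i]) || placed[sire_i[i]]) &&
        (is.na(dam_i[i]) || placed[dam_i[i]])
    }, logical(1)))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) != n) {
    stop("cyclic parentage detected in pedigree", call. = FALSE)
  }

  # connected components over parent-child edges
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) comp[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n)) {
    if (!is.na(sire_i[i])) union_(i, sire_i[i])
    if (!is.na(dam_i[i])) union_(i, dam_i[i])
  }
  roots <- vapply(seq_len(n), find, integer(1))

  # phenotype likelihood per individual per genotype (3 columns WW, Wy, yy)
  phen_lik <- matrix(1, n, 3L, dimnames = list(NULL, GENOTYPES))
  male_obs <- ped$sex == "male" & !is.na(ped$phenotype)
  phen_lik[male_obs & ped$phenotype == "white", "yy"] <- 0
  phen_lik[male_obs & ped$phenotype == "yellow", c("WW", "Wy")] <- 0
  for (i in which(obs)) {
    keep <- GENOTYPES == ped$genotype[i]
    phen_lik[i, !keep] <- 0
  }

  founder_prior <- c(founder_prior_W^2,
                     2 * founder_prior_W * (1 - founder_prior_W),
                     (1 - founder_prior_W)^2)
  # transmission tensor: trans[gs, gd, gc]
  trans <- array(0, c(3, 3, 3), dimnames = list(GENOTYPES, GENOTYPES, GENOTYPES))
  for (gs in GENOTYPES) for (gd in GENOTYPES) {
    trans[gs, gd, ] <- offspring_genotype_distribution(c(gs, gd))[GENOTYPES]
  }

  marg <- matrix(0, n, 3L, dimnames = list(ped$id, GENOTYPES))
  comp_prob <- numeric(0)

  for (root in unique(roots)) {
    members <- which(roots == root)
    if (length(members) > cap) {
      stop("pedigree component of size ", length(members),
           " too large for exact enumeration (cap = ", cap, ")",
           call. = FALSE)
    }
    ord_m <- ord[ord %in% members]
    k <- length(ord_m)
    acc <- matrix(0, k, 3L)
    total <- 0
    assign_g <- integer(k)  # genotype index per position in ord_m
    pos_of <- stats::setNames(seq_len(k), ord_m)

    recurse <- function(pos, w) {
      if (pos > k) {
        total <<- total + w
        for (q in seq_len(k)) acc[q, assign_g[q]] <<- acc[q, assign_g[q]] + w
        return(invisible())
      }
      i <- ord_m[pos]
      for (gi in 1:3) {
        pw <- phen_lik[i, gi]
        if (pw == 0) next
        base <- if (is.na(sire_i[i]) && is.na(dam_i[i])) {
          founder_prior[gi]
        } else if (!is.na(sire_i[i]) && !is.na(dam_i[i])) {
          trans[assign_g[pos_of[[as.character(sire_i[i])]]],
                assign_g[pos_of[[as.character(dam_i[i])]]], gi]
        } else {
          # single known parent: average transmission over the missing
          # parent's founder prior
          known <- if (is.na(sire_i[i])) dam_i[i] else sire_i[i]
          sum(founder_prior *
                trans[assign_g[pos_of[[as.character(known)]]], , gi])
        }
        wnew <- w * base * pw
        if (wnew == 0) next
        assign_g[pos] <<- gi
        recurse(pos + 1L, wnew)
      }
      invisible()
    }
    recurse(1L, 1)

    if (total <= 0) {
      stop("inconsistent pedigree: observations have probability 0 in component containing ",
           ped$id[members[1]], call. = FALSE)
    }
    marg[ord_m, ] <- acc / total
    comp_prob <- c(comp_prob, stats::setNames(total, ped$id[members[1]]))
  }

  out <- data.frame(id = ped$id, p_WW = marg[, "WW"], p_Wy = marg[, "Wy"],
                    p_yy = marg[, "yy"], component = roots,
                    stringsAsFactors = FALSE)
  attr(out, "component_prob") <- comp_prob
  out
}
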