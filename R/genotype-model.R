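#' One-locus two-allele genotype model
#'
#' The hindwing colour locus carries two alleles, dominant `W` and recessive
#' `y`, giving three genotypes `WW`, `Wy`, `yy`. Males express the locus
#' discretely: any `W` copy gives a white hindwing, `yy` gives yellow.
#'
#' @name genotype-model
NULL

GENOTYPES <- c("WW", "Wy", "yy")

# Number of W alleles carried by each genotype.
W_DOSE <- c(WW = 2L, Wy = 1L, yy = 0L)

#' Validate and canonicalise genotype labels
#'
#' @param g Character vector of genotype labels; `"yW"` and `"yW"`-style
#'   orderings are canonicalised to `WW`/`Wy`/`yy`.
#' @return Character vector of canonical labels.
#' @export
as_genotype <- function(g) {
  g <- as.character(g)
  g[g == "yW"] <- "Wy"
  bad <- !(g %in% GENOTYPES)
  if (any(bad)) {
    stop("invalid genotype label(s): ", paste(unique(g[bad]), collapse = ", "),
         call. = FALSE)
  }
  g
}

#' Dominance map from genotype to male hindwing phenotype
#'
#' @param g Genotype labels.
#' @return `"white"` for `WW`/`Wy`, `"yellow"` for `yy`.
#' @export
male_phenotype <- function(g) {
  g <- as_genotype(g)
  ifelse(g == "yy", "yellow", "white")
}

#' Canonical cross label for an unordered parent pair
#'
#' Crosses are symmetric in the parents; the label orders the two genotypes
#' as `WW < Wy < yy`, e.g. `cross_type("yy", "Wy")` is `"Wy x yy"`.
#'
#' @param g1,g2 Parent genotypes.
#' @return Canonical cross label string.
#' @export
cross_type <- function(g1, g2) {
  g1 <- as_genotype(g1)
  g2 <- as_genotype(g2)
  a <- pmin(match(g1, GENOTYPES), match(g2, GENOTYPES))
  b <- pmax(match(g1, GENOTYPES), match(g2, GENOTYPES))
  paste(GENOTYPES[a], "x", GENOTYPES[b])
}

#' All six distinct cross types
#' @return Character vector of the six canonical cross labels.
#' @export
all_cross_types <- function() {
  idx <- which(upper.tri(diag(3), diag = TRUE), arr.ind = TRUE)
  sort(paste(GENOTYPES[idx[, "row"]], "x", GENOTYPES[idx[, "col"]]))
}

parse_cross <- function(cross) {
  if (length(cross) == 2L) return(as_genotype(cross))
  parts <- strsplit(as.character(cross), " x ", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("cross must be a 'g1 x g2' label or a length-2 genotype vector",
         call. = FALSE)
  }
  as_genotype(parts)
}

# Gamete distribution of one parent: P(transmits W).
gamete_p_W <- function(g) W_DOSE[as_genotype(g)] / 2

#' Punnett-square offspring genotype distribution
#'
#' Enumerates the four equally likely gamete combinations of a cross and
#' collapses them to genotype probabilities (e.g. `Wy x Wy` gives
#' 0.25/0.50/0.25 for `WW`/`Wy`/`yy`, the classic 3:1 phenotype ratio).
#'
#' @param cross A cross label (`"Wy x Wy"`) or length-2 genotype vector.
#' @return Named numeric vector over `WW`, `Wy`, `yy`; sums to 1.
#' @export
offspring_genotype_distribution <- function(cross) {
  gg <- parse_cross(cross)
  p1 <- unname(gamete_p_W(gg[1]))
  p2 <- unname(gamete_p_W(gg[2]))
  c(WW = p1 * p2,
    Wy = p1 * (1 - p2) + (1 - p1) * p2,
    yy = (1 - p1) * (1 - p2))
}

#' Male phenotype distribution of a cross
#'
#' Pushes the offspring genotype distribution through the dominance map.
#'
#' @inheritParams offspring_genotype_distribution
#' @return Named numeric vector over `white`, `yellow`; sums to 1.
#' @export
male_phenotype_distribution <- function(cross) {
  d <- offspring_genotype_distribution(cross)
  c(white = unname(d["WW"] + d["Wy"]), yellow = unname(d["yy"]))
}
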