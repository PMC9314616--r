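#!/usr/bin/env Rscript

# Stage 2 -- Mendelian inheritance analysis of the pedigree.
#
# Infers each family's parental cross from its male offspring phenotype
# ratio (binomial maximum likelihood over the six cross types; all-white
# broods are reported as the exact 3-way tie among WW x WW, WW x Wy and
# WW x yy), then tests the pooled segregation of white vs yellow males
# against the model's expected frequencies, and back-traces genotype
# probabilities on a worked pedigree fragment.

library(cryptomorph)

inh <- run_inheritance("results/pedigree.csv")
write.csv(inh$inference, "results/cross_inference.csv", row.names = FALSE)

used <- !inh$families$excluded
cat(sprintf("families used after the offspring filter: %d of %d\n",
            sum(used), nrow(inh$families)))

truth <- read.csv("results/families.csv", stringsAsFactors = FALSE)
cmp <- merge(truth[c("family", "cross", "excluded")],
             inh$inference[c("family", "identifiability_class")], by = "family")
cmp <- cmp[!cmp$excluded, ]
truth_class <- ifelse(cmp$cross %in% c("WW x WW", "WW x Wy", "WW x yy"),
                      "all-white", cmp$cross)
cat(sprintf("cross identifiability class recovered for %.1f%% of used families\n",
            100 * mean(cmp$identifiability_class == truth_class)))

seg <- inh$segregation
cat(sprintf("pooled segregation test: X2 = %.1f on %d df, p = %.3f\n",
            seg$statistic, seg$df, seg$p_value))
jsonlite::write_json(list(statistic = seg$statistic, df = seg$df,
                          p_value = seg$p_value),
                     "results/segregation_test.json",
                     auto_unbox = TRUE, digits = NA)

# back-trace on a three-individual fragment: a white father with a yellow
# son must be heterozygous
ped <- data.frame(id = c("dad", "mum", "son"),
                  sire = c(NA, NA, "dad"), dam = c(NA, NA, "mum"),
                  sex = c("male", "female", "male"),
                  phenotype = c("white", NA, "yellow"))
marg <- propagate_pedigree_genotypes(ped)
write.csv(marg, "results/backtrace_example.csv", row.names = FALSE)
cat(sprintf("back-trace example: P(father Wy | yellow son) = %.3f\n",
            marg$p_Wy[marg$id == "dad"]))
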