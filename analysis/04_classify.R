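#!/usr/bin/env Rscript

# Stage 4 -- genotype classification from image features.
#
# Leave-one-out linear discriminant classification of the three male
# genotypes, the same analysis without UV features (showing that the WW/Wy
# separation lives in the ultraviolet), discriminant scores for plotting,
# and a shadow-feature (random forest) screen of which features carry the
# signal.

library(cryptomorph)

features <- read.csv("results/features.csv", stringsAsFactors = FALSE)

loo <- evaluate_loo(features, features$genotype)
cat(sprintf("LOO linear discriminant accuracy: %.2f%%\n", 100 * loo$accuracy))
print(loo$confusion)
conf <- as.data.frame(loo$confusion)
conf$overall_accuracy <- loo$accuracy
write.csv(conf, "results/confusion.csv", row.names = FALSE)

no_uv <- features[, !grepl("_uv$", names(features))]
loo2 <- evaluate_loo(no_uv, no_uv$genotype)
ww_wy <- no_uv$genotype %in% c("WW", "Wy")
cat(sprintf("without UV features: overall %.2f%%, WW-vs-Wy %.2f%%\n",
            100 * loo2$accuracy,
            100 * mean(loo2$predicted[ww_wy] == no_uv$genotype[ww_wy])))

model <- fit_discriminant(features, features$genotype)
scores <- data.frame(id = features$id, genotype = features$genotype,
                     project(model, features))
write.csv(scores, "results/scores.csv", row.names = FALSE)

imp <- shadow_feature_selection(features, features$genotype,
                                n_iter = 50, seed = 20260930L,
                                num_trees = 300)
write.csv(imp$decisions, "results/importance.csv", row.names = FALSE)
confirmed <- imp$decisions$feature[imp$decisions$status == "confirmed"]
cat("shadow-confirmed features:",
    paste(head(sort(confirmed), 12), collapse = ", "),
    if (length(confirmed) > 12) "..." else "", "\n")
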