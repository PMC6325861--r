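#!/usr/bin/env Rscript
# Which features carry the signal? Single-feature impact ranking, CFS
# best-first subset, PCA-based ranking, pairwise correlations, and the
# exhaustive search over all 511 feature subsets with naive Bayes.

suppressPackageStartupMessages(library(hpscore))

d <- read_feature_matrix("results/dataset.tsv")
plan <- split_plan(k = 5, seed = 4)
nb <- classifier_factory("nb")

imp <- rank_feature_impact(d, nb, plan)
cat("single-feature impact (rank 1 = high impact):\n")
print(imp[order(imp$rank), ])
write.table(imp, "results/impact_rank.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cfs <- cfs_select(d)
cat(sprintf("CFS subset: {%s}, merit %.4f\n", paste(cfs, collapse = ","),
            attr(cfs, "merit")))

pca <- pca_rank(d)
cat("PCA ranking (most important first):", pca$ranking, "\n")

cors <- pearson_feature_correlations(d)
cat("strongest feature correlations:\n")
print(head(cors[order(-abs(cors$pearson_r)), ], 5), row.names = FALSE)
write.table(cors, "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ex <- exhaustive_subset_search(d, nb, plan)
cat(sprintf("exhaustive search: %d subsets; best {%s} at %.2f%% (full set %.2f%%)\n",
            nrow(ex$table), paste(ex$best$subset, collapse = ","),
            100 * ex$best$accuracy,
            100 * ex$table$accuracy[ex$table$n_features == 9]))
write.table(ex$table, "results/subset_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/impact_rank.tsv, results/correlations.tsv, results/subset_table.tsv\n")
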