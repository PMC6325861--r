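#!/usr/bin/env Rscript
# Profile-similarity structure and significance: Jaccard similarity of the
# nine-bit profiles (long-format export for plotting distance per protein)
# and one-way ANOVA of score frequencies across features within each class.

suppressPackageStartupMessages(library(hpscore))

d <- read_feature_matrix("results/dataset.tsv")

sim <- jaccard_matrix(d)
lg <- jaccard_long(sim)
cat(sprintf("Jaccard matrix: %d x %d; %d pairs; %d all-zero-profile pairs\n",
            nrow(sim$values), ncol(sim$values), nrow(lg),
            sim$zero_profile_pairs))
cat(sprintf("similarity range: %.3f .. %.3f (within-positive mean %.3f, within-negative mean %.3f)\n",
            min(lg$jaccard), max(lg$jaccard),
            mean(sim$values[d$label == "positive", d$label == "positive"]),
            mean(sim$values[d$label == "negative", d$label == "negative"])))
write.table(lg, "results/jaccard_long.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (cl in c("positive", "negative")) {
  a <- anova_by_feature(d, cl)
  cat(sprintf("ANOVA across features, %s class: F = %.2f, p = %.3g, significant at 0.05: %s\n",
              cl, a$F, a$p, a$significant))
}
cat("wrote results/jaccard_long.tsv\n")
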