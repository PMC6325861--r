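#!/usr/bin/env Rscript
# Train and evaluate the four classifier families on the nine-bit vectors:
# stratified 10-fold cross-validation for all four, plus the repeated
# 66%-split protocol for the pocket perceptron (mean/max/min accuracy over
# the iteration trace).

suppressPackageStartupMessages(library(hpscore))

d <- read_feature_matrix("results/dataset.tsv")
plan <- split_plan(k = 10, seed = 3)

fits <- list(
  perceptron = classifier_factory("perceptron",
                                  config = perceptron_config(include_bias = TRUE)),
  naive_bayes = classifier_factory("nb"),
  decision_tree = classifier_factory("tree"),
  svm_linear = classifier_factory("svm", kernel = "linear"),
  svm_poly = classifier_factory("svm", kernel = "poly", degree = 2),
  svm_npoly = classifier_factory("svm", kernel = "normalized_poly",
                                 degree = 2)
)

cv <- lapply(fits, function(f) stratified_kfold_cv(d, f, plan))
tab <- data.frame(
  algorithm = names(cv),
  accuracy_pct = sapply(cv, function(r) round(100 * r$pooled$accuracy, 2)),
  sensitivity_pct = sapply(cv, function(r)
    round(100 * r$pooled$sensitivity, 2)),
  specificity_pct = sapply(cv, function(r)
    round(100 * r$pooled$specificity, 2)),
  f1_pct = sapply(cv, function(r) round(100 * r$pooled$f1, 2)),
  mcc_pct = sapply(cv, function(r) round(100 * r$pooled$mcc, 2)),
  row.names = NULL
)
cat("10-fold CV (pooled):\n")
print(tab)
write.table(tab, "results/cv_metrics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# repeated random 66% splits, perceptron with the documented parameters
rs_plan <- split_plan("repeated_split", train_fraction = 0.66,
                      iterations = 1000, seed = 3)
rs <- repeated_random_split_eval(d, fits$perceptron, rs_plan)
cat(sprintf("perceptron over 1000 random 66%% splits: mean %.2f%%, max %.2f%%, min %.2f%%\n",
            100 * rs$mean, 100 * rs$max, 100 * rs$min))
write.table(data.frame(iteration = seq_along(rs$trace),
                       accuracy = rs$trace),
            "results/perceptron_trace.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/cv_metrics.tsv, results/perceptron_trace.tsv\n")
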