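#' Evaluation split plan
#'
#' @param protocol \code{"kfold"} (stratified k-fold cross-validation) or
#'   \code{"repeated_split"} (repeated random train/test splits, averaged).
#' @param k Number of folds. Default 10.
#' @param train_fraction Training fraction for repeated splits. Default 0.66,
#'   the setting attached to the headline perceptron run; 0.8 matches the
#'   80/20 protocol.
#' @param iterations Number of repeated splits. Default 1000.
#' @param stratified Preserve class proportions in folds/splits. Default TRUE.
#' @param seed Integer RNG seed.
#' @return A list of class \code{hp_split_plan}.
#' @export
split_plan <- function(protocol = c("kfold", "repeated_split"), k = 10L,
                       train_fraction = 0.66, iterations = 1000L,
                       stratified = TRUE, seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(k >= 2, train_fraction > 0, train_fraction < 1, iterations >= 1)
  plan <- list(protocol = protocol, k = as.integer(k),
               train_fraction = train_fraction,
               iterations = as.integer(iterations),
               stratified = isTRUE(stratified), seed = as.integer(seed))
  class(plan) <- "hp_split_plan"
  plan
}

# Fold assignment: every fold receives floor(n_c/k) rows of class c, and the
# remainder rows go to the folds with the smallest running totals, keeping
# overall fold sizes within one row of n/k even under class imbalance.
assign_folds <- function(labels, k, stratified, seed) {
  n <- length(labels)
  withr::with_seed(seed, {
    folds <- integer(n)
    if (!stratified) {
      folds <- rep_len(seq_len(k), n)[sample.int(n)]
      return(folds)
    }
    load <- integer(k)
    for (cl in c("positive", "negative")) {
      idx <- which(labels == cl)
      if (length(idx) == 0L) next
      if (length(idx) < k) {
        stop(sprintf("class '%s' has %d rows, fewer than k = %d folds",
                     cl, length(idx), k), call. = FALSE)
      }
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% k
      rem <- length(idx) - base * k
      sizes <- rep(base, k)
      if (rem > 0L) {
        extra <- order(load, seq_len(k))[seq_len(rem)]
        sizes[extra] <- sizes[extra] + 1L
      }
      folds[idx] <- rep(seq_len(k), times = sizes)
      load <- load + sizes
    }
    folds
  })
}

#' Stratified k-fold cross-validation
#'
#' Partitions the dataset into k pairwise-disjoint folds whose union is the
#' whole dataset and whose per-class proportions match the global ones to
#' within one row; each fold serves once as the test set, so no training row
#' ever appears in its own test fold. Reports per-fold metrics, the pooled
#' metrics over summed confusion counts, and the fold-averaged accuracy.
#'
#' @param data data.frame with feature columns \code{f*} and \code{label}.
#' @param fit Classifier factory: \code{function(train) -> model} where the
#'   model answers \code{predict(model, test)}.
#' @param plan An [split_plan()] with \code{protocol = "kfold"}.
#' @return List with \code{per_fold} (list of [compute_metrics()] reports),
#'   \code{pooled}, \code{fold_accuracy}, \code{mean_fold_accuracy},
#'   \code{folds} (assignment vector).
#' @export
stratified_kfold_cv <- function(data, fit, plan = split_plan()) {
  stopifnot(nrow(data) >= plan$k)
  folds <- assign_folds(data$label, plan$k, plan$stratified, plan$seed)
  per_fold <- vector("list", plan$k)
  total <- list(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (f in seq_len(plan$k)) {
    test <- data[folds == f, , drop = FALSE]
    train <- data[folds != f, , drop = FALSE]
    model <- fit(train)
    cc <- confusion_counts(test$label, stats::predict(model, test))
    per_fold[[f]] <- compute_metrics(cc)
    total <- Map(`+`, total, cc[c("tp", "tn", "fp", "fn")])
  }
  class(total) <- "hp_confusion"
  fold_acc <- vapply(per_fold, function(m) m$accuracy, numeric(1))
  list(per_fold = per_fold, pooled = compute_metrics(total),
       fold_accuracy = fold_acc, mean_fold_accuracy = mean(fold_acc),
       folds = folds)
}

#' Repeated random-split evaluation
#'
#' Draws \code{plan$iterations} independent seeded train/test splits at
#' \code{plan$train_fraction}, trains a fresh model per split, evaluates on
#' the held-out rows only, and summarizes held-out accuracy as mean, maximum
#' and minimum over the trace.
#'
#' @inheritParams stratified_kfold_cv
#' @param plan An [split_plan()] with \code{protocol = "repeated_split"}.
#' @return List with \code{mean}, \code{max}, \code{min} and the
#'   per-iteration accuracy \code{trace}.
#' @export
repeated_random_split_eval <- function(data, fit, plan) {
  stopifnot(identical(plan$protocol, "repeated_split"))
  n <- nrow(data)
  trace <- numeric(plan$iterations)
  withr::with_seed(plan$seed, {
    for (it in seq_len(plan$iterations)) {
      if (plan$stratified) {
        train_idx <- unlist(lapply(c("positive", "negative"), function(cl) {
          idx <- which(data$label == cl)
          sample(idx, round(plan$train_fraction * length(idx)))
        }))
      } else {
        train_idx <- sample.int(n, round(plan$train_fraction * n))
      }
      test_idx <- setdiff(seq_len(n), train_idx)
      if (length(train_idx) == 0L || length(test_idx) == 0L) {
        stop("train or test side of the split is empty", call. = FALSE)
      }
      model <- fit(data[train_idx, , drop = FALSE])
      pred <- stats::predict(model, data[test_idx, , drop = FALSE])
      trace[it] <- mean(pred == data$label[test_idx])
    }
  })
  list(mean = mean(trace), max = max(trace), min = min(trace), trace = trace)
}
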