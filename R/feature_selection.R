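feature_ids <- function(data) {
  as.integer(sub("^f", "", feature_cols(data)))
}

subset_key <- function(s) paste(sprintf("%02d", sort(s)), collapse = ",")

#' CFS merit of a feature subset
#'
#' \eqn{M_S = k \bar r_{cf} / \sqrt{k + k(k-1) \bar r_{ff}}} where
#' \eqn{\bar r_{cf}} is the mean absolute feature--class Pearson correlation
#' over the k subset features and \eqn{\bar r_{ff}} the mean absolute
#' feature--feature correlation among them.
#'
#' @param data data.frame with feature columns \code{f*} and \code{label}.
#' @param subset Integer vector of feature ids.
#' @return Numeric merit.
#' @export
cfs_merit <- function(data, subset) {
  y <- as.integer(data$label == "positive")
  x <- as.matrix(data[paste0("f", subset)])
  k <- length(subset)
  rcf <- mean(abs(vapply(seq_len(k),
                         function(j) stats::cor(x[, j], y), numeric(1))))
  rff <- if (k == 1L) 0 else {
    pairs <- utils::combn(k, 2)
    mean(abs(apply(pairs, 2,
                   function(p) stats::cor(x[, p[1]], x[, p[2]]))))
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Correlation-based feature selection (best-first search)
#'
#' Forward best-first search over feature subsets maximizing the CFS merit
#' ([cfs_merit()]): high mean correlation with the class, low redundancy
#' among the selected features. The search expands the best unexpanded
#' subset and stops after \code{patience} consecutive expansions that fail
#' to improve the best merit. Ties break toward the lexicographically
#' smaller subset, so the result is deterministic. Constant feature columns
#' are excluded with a warning (their correlation is undefined).
#'
#' @inheritParams cfs_merit
#' @param patience Consecutive non-improving expansions allowed. Default 5.
#' @return Sorted integer vector of selected feature ids, with the merit in
#'   \code{attr(, "merit")}.
#' @export
cfs_select <- function(data, patience = 5L) {
  ids <- feature_ids(data)
  if (length(ids) < 1L) stop("no feature columns", call. = FALSE)
  if (!all(c("positive", "negative") %in% data$label)) {
    stop("both classes must be present", call. = FALSE)
  }
  const <- ids[vapply(ids, function(j) {
    v <- data[[paste0("f", j)]]
    all(v == v[1])
  }, logical(1))]
  if (length(const)) {
    warning("excluding constant feature columns: ",
            paste0("f", const, collapse = ", "), call. = FALSE)
    ids <- setdiff(ids, const)
  }
  if (length(ids) == 0L) stop("all feature columns are constant",
                              call. = FALSE)
  if (length(ids) == 1L) {
    out <- ids
    attr(out, "merit") <- cfs_merit(data, ids)
    return(out)
  }

  open <- lapply(ids, function(j) list(s = j, m = cfs_merit(data, j)))
  visited <- new.env(parent = emptyenv())
  for (o in open) assign(subset_key(o$s), TRUE, envir = visited)
  pick_best <- function(lst) {
    ms <- vapply(lst, function(o) o$m, numeric(1))
    keys <- vapply(lst, function(o) subset_key(o$s), character(1))
    order(-ms, keys)[1]
  }
  best <- open[[pick_best(open)]]
  stalls <- 0L
  while (length(open) > 0L && stalls < patience) {
    i <- pick_best(open)
    node <- open[[i]]
    open[[i]] <- NULL
    improved <- FALSE
    for (j in setdiff(ids, node$s)) {
      s2 <- sort(c(node$s, j))
      key <- subset_key(s2)
      if (exists(key, envir = visited)) next
      assign(key, TRUE, envir = visited)
      cand <- list(s = s2, m = cfs_merit(data, s2))
      open[[length(open) + 1L]] <- cand
      if (cand$m > best$m) {
        best <- cand
        improved <- TRUE
      }
    }
    stalls <- if (improved) 0L else stalls + 1L
  }
  out <- sort(best$s)
  attr(out, "merit") <- best$m
  out
}

#' PCA-based feature ranking
#'
#' Principal components of the centered score matrix; each feature's
#' importance is \eqn{\sum_c |loading_{jc}| \cdot v_c} with \eqn{v_c} the
#' variance fraction of component c, projecting component importance back
#' onto the original features. Component signs follow the convention that
#' the largest-magnitude loading is positive.
#'
#' @param data data.frame with feature columns \code{f*} (>= 2 rows).
#' @return List with \code{ranking} (feature ids, most important first),
#'   \code{importance}, \code{var_fraction}, \code{rotation}.
#' @export
pca_rank <- function(data) {
  if (nrow(data) < 2L) stop("need at least 2 rows", call. = FALSE)
  ids <- feature_ids(data)
  x <- as.matrix(data[paste0("f", ids)])
  if (all(apply(x, 2, stats::var) == 0)) {
    stop("zero-variance matrix: PCA undefined", call. = FALSE)
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pr$rotation
  for (c in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, c])), c] < 0) rot[, c] <- -rot[, c]
  }
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  importance <- as.vector(abs(rot) %*% vf)
  names(importance) <- paste0("f", ids)
  ord <- order(-importance, ids)
  list(ranking = ids[ord], importance = importance,
       var_fraction = vf, rotation = rot)
}

# Held-out accuracy of a fit factory under a plan (pooled for k-fold CV,
# mean over iterations for repeated splits).
evaluate_plan <- function(data, fit, plan) {
  if (identical(plan$protocol, "kfold")) {
    stratified_kfold_cv(data, fit, plan)$pooled$accuracy
  } else {
    repeated_random_split_eval(data, fit, plan)$mean
  }
}

subset_data <- function(data, subset) {
  data[c("protein_id", paste0("f", sort(subset)),
         intersect("label", names(data)))]
}

#' Exhaustive feature-subset search
#'
#' Evaluates all \eqn{2^m - 1} non-empty feature subsets under the same
#' seeded evaluation plan and returns the best-accuracy subset, ties going
#' first to the smaller subset and then to the lexicographically smaller
#' one. With the identical plan seed every subset sees the same folds, so
#' the full feature set is always a candidate and the best accuracy can
#' never fall below it.
#'
#' @inheritParams stratified_kfold_cv
#' @return List with \code{best} (list: subset, accuracy, n_features) and
#'   \code{table} (data.frame over all subsets, in evaluation order).
#' @export
exhaustive_subset_search <- function(data, fit, plan = split_plan()) {
  ids <- feature_ids(data)
  m <- length(ids)
  if (m < 1L) stop("no feature columns", call. = FALSE)
  subsets <- unlist(lapply(seq_len(m), function(k)
    utils::combn(ids, k, simplify = FALSE)), recursive = FALSE)
  acc <- vapply(subsets, function(s)
    evaluate_plan(subset_data(data, s), fit, plan), numeric(1))
  tab <- data.frame(
    subset = vapply(subsets, function(s) paste(s, collapse = ","),
                    character(1)),
    n_features = lengths(subsets),
    accuracy = acc,
    stringsAsFactors = FALSE
  )
  keys <- vapply(subsets, subset_key, character(1))
  best_i <- order(-acc, lengths(subsets), keys)[1]
  list(best = list(subset = subsets[[best_i]], accuracy = acc[best_i],
                   n_features = length(subsets[[best_i]])),
       table = tab)
}

#' Pairwise Pearson correlations between features
#'
#' All unordered feature pairs with the Pearson correlation of the binary
#' columns (equivalently the phi coefficient) and the two-tailed p-value
#' from the t distribution with n - 2 degrees of freedom. Constant columns
#' yield \code{NA} with a warning.
#'
#' @param data data.frame with feature columns \code{f*} (>= 3 rows).
#' @return data.frame with columns \code{feature_i}, \code{feature_j},
#'   \code{pearson_r}, \code{p_two_tailed}.
#' @export
pearson_feature_correlations <- function(data) {
  if (nrow(data) < 3L) stop("need at least 3 rows", call. = FALSE)
  ids <- feature_ids(data)
  pairs <- utils::combn(ids, 2)
  warned <- FALSE
  res <- apply(pairs, 2, function(p) {
    x <- data[[paste0("f", p[1])]]
    y <- data[[paste0("f", p[2])]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warned <<- TRUE
      return(c(NA_real_, NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    c(unname(ct$estimate), ct$p.value)
  })
  if (warned) warning("constant feature column(s): correlation undefined",
                      call. = FALSE)
  data.frame(feature_i = pairs[1, ], feature_j = pairs[2, ],
             pearson_r = res[1, ], p_two_tailed = res[2, ])
}

#' Single-feature impact ranking
#'
#' Evaluates every feature alone under the plan and ranks by held-out
#' accuracy, Rank 1 = highest impact. Competition ranking: tied features
#' share the better rank and the following rank is skipped.
#'
#' @inheritParams stratified_kfold_cv
#' @return data.frame with columns \code{feature}, \code{accuracy},
#'   \code{rank}, ordered by feature id.
#' @export
rank_feature_impact <- function(data, fit, plan = split_plan()) {
  ids <- feature_ids(data)
  acc <- vapply(ids, function(j)
    evaluate_plan(subset_data(data, j), fit, plan), numeric(1))
  rank <- vapply(acc, function(a) 1L + sum(acc > a), integer(1))
  data.frame(feature = ids, accuracy = acc, rank = rank)
}
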