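#' Jaccard similarity matrix of binary feature profiles
#'
#' \eqn{J(x, y) = M_{11} / (M_{11} + M_{10} + M_{01})} over the nine-bit
#' profiles, where \eqn{M_{11}} counts features scored 1 in both proteins
#' and \eqn{M_{10}}, \eqn{M_{01}} those scored 1 in exactly one. Two
#' all-zero profiles are identical, so their similarity is defined as 1
#' (flagged in the result, since some conventions use 0). The complement
#' \eqn{1 - J} is the Jaccard distance, a metric.
#'
#' @param data data.frame with \code{protein_id} and feature columns.
#' @return List of class \code{hp_jaccard} with \code{ids}, \code{values}
#'   (n x n similarity matrix) and \code{zero_profile_pairs} (count of pairs
#'   scored by the all-zero convention).
#' @export
#' @examples
#' d <- generate_labeled_dataset(dataset_spec(n_positive = 5, n_negative = 5))
#' j <- jaccard_matrix(d)
#' j$values[1:3, 1:3]
jaccard_matrix <- function(data) {
  if (nrow(data) < 1L) stop("need at least one row", call. = FALSE)
  x <- as.matrix(data[feature_cols(data)])
  storage.mode(x) <- "double"
  m11 <- tcrossprod(x)
  r <- rowSums(x)
  denom <- outer(r, r, "+") - m11
  j <- ifelse(denom == 0, 1, m11 / pmax(denom, 1e-300))
  dimnames(j) <- list(data$protein_id, data$protein_id)
  out <- list(ids = data$protein_id, values = j,
              zero_profile_pairs = (sum(denom == 0) - sum(r == 0)) / 2)
  class(out) <- "hp_jaccard"
  out
}

#' Long-format Jaccard table
#'
#' @param sim An [jaccard_matrix()] result.
#' @return data.frame with \code{id1}, \code{id2}, \code{jaccard},
#'   \code{distance} for every unordered pair.
#' @export
jaccard_long <- function(sim) {
  stopifnot(inherits(sim, "hp_jaccard"))
  n <- length(sim$ids)
  idx <- which(upper.tri(sim$values), arr.ind = TRUE)
  data.frame(id1 = sim$ids[idx[, 1]], id2 = sim$ids[idx[, 2]],
             jaccard = sim$values[idx],
             distance = 1 - sim$values[idx],
             stringsAsFactors = FALSE)
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way analysis of variance,
#' \eqn{F = MS_{between} / MS_{within}}, with the p-value from the F
#' distribution. When every group is constant with zero within-group
#' variance the statistic is undefined and the result is flagged degenerate
#' rather than reported as a number.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @param alpha Significance level. Default 0.05.
#' @return List with \code{F}, \code{p}, \code{significant},
#'   \code{degenerate}, \code{df_between}, \code{df_within}.
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least two values",
                            call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  df_b <- length(groups) - 1L
  df_w <- length(values) - length(groups)
  within_var <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                           numeric(1)))
  if (within_var == 0) {
    return(list(F = NA_real_, p = NA_real_, significant = NA,
                degenerate = TRUE, df_between = df_b, df_within = df_w))
  }
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = ft$p.value,
       significant = ft$p.value < alpha, degenerate = FALSE,
       df_between = df_b, df_within = df_w)
}

#' Per-class, per-feature ANOVA groupings
#'
#' Default grouping for the significance check: within one class, the nine
#' feature score columns form nine groups and the ANOVA asks whether their
#' means (score frequencies) differ.
#'
#' @param data Labeled feature matrix.
#' @param class_label \code{"positive"} or \code{"negative"}.
#' @param alpha Significance level.
#' @return [anova_oneway()] result.
#' @export
anova_by_feature <- function(data, class_label, alpha = 0.05) {
  rows <- data[data$label == class_label, ]
  groups <- lapply(feature_cols(data), function(cn) as.numeric(rows[[cn]]))
  anova_oneway(groups, alpha)
}
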