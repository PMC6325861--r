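entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# information gain and gain ratio of splitting y by binary feature x
split_criterion <- function(x, y, use_gain_ratio) {
  n <- length(y)
  n1 <- sum(x == 1)
  n0 <- n - n1
  if (n0 == 0L || n1 == 0L) return(NA_real_)   # degenerate split
  h <- entropy_bits(tabulate(y + 1L, 2L))
  h0 <- entropy_bits(tabulate(y[x == 0] + 1L, 2L))
  h1 <- entropy_bits(tabulate(y[x == 1] + 1L, 2L))
  gain <- h - (n0 / n) * h0 - (n1 / n) * h1
  if (!use_gain_ratio) return(gain)
  split_info <- entropy_bits(c(n0, n1))
  gain / split_info
}

grow_tree <- function(x, y, available, min_leaf, use_gain_ratio) {
  n_pos <- sum(y == 1L)
  n_neg <- length(y) - n_pos
  # ties predict the negative (majority) class
  leaf <- list(leaf = TRUE, prediction = if (n_pos > n_neg) 1L else 0L,
               n = length(y), n_positive = n_pos)
  if (n_pos == 0L || n_neg == 0L) return(leaf)           # pure node
  if (length(y) < min_leaf) return(leaf)
  usable <- available[apply(x[, available, drop = FALSE], 2,
                            function(v) any(v != v[1]))]
  if (length(usable) == 0L) return(leaf)                 # path exhausted
  crit <- vapply(usable, function(j)
    split_criterion(x[, j], y, use_gain_ratio), numeric(1))
  best <- usable[which.max(crit)]   # which.max takes the first (lowest id)
  rest <- setdiff(available, best)
  left <- x[, best] == 0
  list(leaf = FALSE, feature = best, n = length(y),
       left = grow_tree(x[left, , drop = FALSE], y[left], rest,
                        min_leaf, use_gain_ratio),
       right = grow_tree(x[!left, , drop = FALSE], y[!left], rest,
                         min_leaf, use_gain_ratio))
}

#' Fit a decision tree on binary features
#'
#' Recursive binary partitioning in the C4.5 style: each node splits on the
#' feature with the highest gain ratio (information gain divided by split
#' information; plain information gain when \code{use_gain_ratio = FALSE}),
#' ties going to the lowest feature index. Growth stops at pure nodes, when
#' every feature on the path is used or constant, or when a node holds fewer
#' than \code{min_leaf} rows. Leaves predict the majority class, ties to
#' negative. No pruning is applied.
#'
#' @param train data.frame with feature columns \code{f*} and \code{label}.
#' @param min_leaf Minimum node size eligible for splitting. Default 2.
#' @param use_gain_ratio Use gain ratio (TRUE) or raw information gain.
#' @return \code{hp_tree} model; \code{$root} is the nested node list.
#' @export
fit_decision_tree <- function(train, min_leaf = 2L, use_gain_ratio = TRUE) {
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  if (min_leaf < 1L) stop("min_leaf must be >= 1", call. = FALSE)
  d <- design(train)
  root <- grow_tree(d$x, d$y, seq_along(d$features), min_leaf,
                    use_gain_ratio)
  model <- list(root = root, features = d$features,
                min_leaf = as.integer(min_leaf),
                use_gain_ratio = isTRUE(use_gain_ratio),
                training_accuracy = NA_real_)
  class(model) <- c("hp_tree", "hp_model")
  model$training_accuracy <- training_accuracy(model, train)
  model
}

predict_node <- function(node, x, idx, out) {
  if (node$leaf) {
    out[idx] <- node$prediction
    return(out)
  }
  left <- x[idx, node$feature] == 0
  if (any(left))  out <- predict_node(node$left, x, idx[left], out)
  if (any(!left)) out <- predict_node(node$right, x, idx[!left], out)
  out
}

#' @export
predict.hp_tree <- function(object, newdata, ...) {
  x <- newdata_matrix(object, newdata)
  out <- integer(nrow(x))
  out <- predict_node(object$root, x, seq_len(nrow(x)), out)
  as_label(out)
}

tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}
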