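#' Fit a Bernoulli naive Bayes classifier
#'
#' Class priors are empirical frequencies; per-feature Bernoulli
#' conditionals use additive (Laplace) smoothing:
#' \eqn{\theta_{jc} = (n_{jc} + \alpha) / (n_c + 2\alpha)}. Prediction is the
#' maximum-posterior class in log space; exact posterior ties (including the
#' degenerate case where both classes have zero likelihood under
#' \code{laplace_alpha = 0}) resolve to the negative class.
#'
#' @param train data.frame with feature columns \code{f*} and \code{label}.
#' @param laplace_alpha Non-negative smoothing constant. Default 1.
#' @return \code{hp_nbayes} model.
#' @export
fit_bernoulli_nb <- function(train, laplace_alpha = 1.0) {
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  if (laplace_alpha < 0) stop("laplace_alpha must be >= 0", call. = FALSE)
  d <- design(train)
  a <- laplace_alpha
  n_pos <- sum(d$y == 1L)
  n_neg <- sum(d$y == 0L)
  theta <- rbind(
    negative = (colSums(d$x[d$y == 0L, , drop = FALSE]) + a) / (n_neg + 2 * a),
    positive = (colSums(d$x[d$y == 1L, , drop = FALSE]) + a) / (n_pos + 2 * a)
  )
  model <- list(prior = c(negative = n_neg, positive = n_pos) / nrow(d$x),
                theta = theta, laplace_alpha = a, features = d$features,
                training_accuracy = NA_real_)
  class(model) <- c("hp_nbayes", "hp_model")
  model$training_accuracy <- training_accuracy(model, train)
  model
}

# Sentinel for log(0): finite so that 0 * log(0) contributes 0 in the
# matrix product, yet far below any attainable log-likelihood, preserving
# the zero-probability short-circuit when laplace_alpha = 0.
NB_LOG_ZERO <- -1e10

nb_log_joint <- function(object, x) {
  out <- sapply(c("negative", "positive"), function(cl) {
    th <- object$theta[cl, ]
    ll <- x %*% ifelse(th > 0, log(th), NB_LOG_ZERO) +
      (1 - x) %*% ifelse(th < 1, log1p(-th), NB_LOG_ZERO)
    pr <- object$prior[cl]
    drop(ll) + if (pr > 0) log(pr) else NB_LOG_ZERO
  })
  matrix(out, ncol = 2, dimnames = list(NULL, c("negative", "positive")))
}

#' @export
predict.hp_nbayes <- function(object, newdata,
                              type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  x <- newdata_matrix(object, newdata)
  lj <- nb_log_joint(object, x)
  if (type == "posterior") {
    post <- t(apply(lj, 1, function(v) {
      m <- max(v)
      exp(v - m) / sum(exp(v - m))
    }))
    colnames(post) <- c("negative", "positive")
    return(post)
  }
  # strictly greater: ties (equal log joints) go to the negative class
  as_label(as.integer(lj[, "positive"] > lj[, "negative"]))
}
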