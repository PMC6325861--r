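#' Pocket perceptron configuration
#'
#' @param eta Positive learning rate. Default 0.2.
#' @param n_iterations Number of single-example presentations (examples are
#'   visited in seeded-shuffled epochs). Default 1000.
#' @param include_bias Append a constant bias input. Off by default, so the
#'   weight vector has exactly one entry per feature; without a bias the
#'   all-zero input always falls on the negative side.
#' @param seed Integer seed for the random initial weights and the epoch
#'   shuffles.
#' @return A list of class \code{hp_perceptron_config}.
#' @export
perceptron_config <- function(eta = 0.2, n_iterations = 1000L,
                              include_bias = FALSE, seed = 1L) {
  stopifnot(eta > 0, n_iterations >= 0)
  cfg <- list(eta = eta, n_iterations = as.integer(n_iterations),
              include_bias = isTRUE(include_bias), seed = as.integer(seed))
  class(cfg) <- "hp_perceptron_config"
  cfg
}

#' Fit a pocket perceptron
#'
#' Online perceptron with unit-step activation: on each presentation of an
#' example \eqn{(x, y)} the weights update as
#' \eqn{w \leftarrow w + \eta (y - \hat y) x}. The pocket stores the weights
#' with the best training accuracy seen so far and the returned model
#' predicts with those, which bounds the error even on non-separable data.
#' Weights are initialized uniformly on \[-1, 1\] from \code{config$seed}.
#'
#' @param train data.frame with feature columns \code{f*} and a \code{label}
#'   column.
#' @param config A [perceptron_config()].
#' @return \code{hp_perceptron} model; \code{$trace} holds the pocket
#'   training accuracy after every presentation.
#' @export
#' @examples
#' d <- generate_labeled_dataset(dataset_spec(n_positive = 20, n_negative = 30))
#' m <- fit_pocket_perceptron(d, perceptron_config(n_iterations = 200))
#' m$training_accuracy
fit_pocket_perceptron <- function(train, config = perceptron_config()) {
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  d <- design(train)
  x <- d$x
  if (config$include_bias) x <- cbind(x, bias = 1)
  y <- d$y
  n <- nrow(x)

  withr::with_seed(config$seed, {
    w <- stats::runif(ncol(x), -1, 1)
    acc <- function(w) mean(as.integer(x %*% w > 0) == y)
    pocket <- w
    pocket_acc <- acc(w)
    trace <- numeric(config$n_iterations)
    order_idx <- integer(0)
    for (t in seq_len(config$n_iterations)) {
      if (length(order_idx) == 0L) order_idx <- sample.int(n)
      i <- order_idx[1]
      order_idx <- order_idx[-1]
      yhat <- as.integer(sum(w * x[i, ]) > 0)
      if (yhat != y[i]) {
        w <- w + config$eta * (y[i] - yhat) * x[i, ]
        a <- acc(w)
        if (a > pocket_acc) {
          pocket <- w
          pocket_acc <- a
        }
      }
      trace[t] <- pocket_acc
    }
  })

  model <- list(weights = pocket, initial_weights = NULL,
                features = d$features, include_bias = config$include_bias,
                training_accuracy = pocket_acc, trace = trace,
                config = config)
  model$initial_weights <- local({
    withr::with_seed(config$seed, stats::runif(ncol(x), -1, 1))
  })
  class(model) <- c("hp_perceptron", "hp_model")
  model
}

#' @export
predict.hp_perceptron <- function(object, newdata, type = c("class", "score"),
                                  ...) {
  type <- match.arg(type)
  x <- newdata_matrix(object, newdata)
  if (object$include_bias) x <- cbind(x, bias = 1)
  s <- drop(x %*% object$weights)
  if (type == "score") return(s)
  as_label(as.integer(s > 0))
}
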