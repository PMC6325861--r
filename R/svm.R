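kernel_fun <- function(kernel, degree, gamma) {
  poly <- function(a, b) (tcrossprod(a, b) + 1)^degree
  switch(kernel,
    linear = function(a, b) tcrossprod(a, b),
    poly = poly,
    rbf = function(a, b) {
      an <- rowSums(a^2); bn <- rowSums(b^2)
      d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
      exp(-gamma * pmax(d2, 0))
    },
    normalized_poly = function(a, b) {
      k <- poly(a, b)
      ka <- (rowSums(a^2) + 1)^degree
      kb <- (rowSums(b^2) + 1)^degree
      k / sqrt(outer(ka, kb))
    },
    stop("unknown kernel: ", kernel, call. = FALSE)
  )
}

#' Fit a soft-margin SVM by sequential minimal optimization
#'
#' Solves the dual soft-margin problem with Platt-style SMO: working pairs
#' of Lagrange multipliers are optimized analytically until no example
#' violates the KKT conditions beyond \code{tol} for \code{max_passes}
#' consecutive sweeps. Pairwise updates keep \eqn{\sum_i \alpha_i y_i = 0}
#' exact and every \eqn{\alpha_i} clipped to \[0, C\]. The partner index in
#' each pair is drawn from a seeded RNG, so the fit is deterministic given
#' (data, configuration, seed). Decision values of exactly zero classify as
#' negative.
#'
#' @param train data.frame with feature columns \code{f*} and \code{label};
#'   both classes must be present.
#' @param kernel One of \code{"linear"}, \code{"poly"} (\eqn{(x\cdot y+1)^d}),
#'   \code{"rbf"} (\eqn{\exp(-\gamma\|x-y\|^2)}), \code{"normalized_poly"}
#'   (polynomial kernel normalized to unit self-similarity).
#' @param degree Polynomial degree. Default 3.
#' @param gamma RBF width. Default 0.5.
#' @param C Soft-margin box constraint. Default 1.
#' @param tol KKT violation tolerance. Default 1e-3.
#' @param max_passes Consecutive full sweeps without an update required to
#'   declare convergence. Default 5.
#' @param max_sweeps Hard cap on full sweeps. Default 200.
#' @param seed Integer seed for partner selection.
#' @return \code{hp_svm} model with multipliers \code{$alpha}, offset
#'   \code{$b} and the training rows (needed by the kernel at prediction).
#' @export
fit_svm_smo <- function(train, kernel = c("linear", "poly", "rbf",
                                          "normalized_poly"),
                        degree = 3, gamma = 0.5, C = 1.0, tol = 1e-3,
                        max_passes = 5L, max_sweeps = 200L, seed = 1L) {
  kernel <- match.arg(kernel)
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  d <- design(train)
  if (length(unique(d$y)) < 2L) {
    stop("SVM training requires both classes", call. = FALSE)
  }
  x <- d$x
  y <- ifelse(d$y == 1L, 1, -1)
  n <- nrow(x)
  kf <- kernel_fun(kernel, degree, gamma)
  K <- kf(x, x)

  alpha <- numeric(n)
  b <- 0
  withr::with_seed(as.integer(seed), {
    passes <- 0L
    sweeps <- 0L
    while (passes < max_passes && sweeps < max_sweeps) {
      changed <- 0L
      for (i in seq_len(n)) {
        Ei <- sum(alpha * y * K[, i]) + b - y[i]
        if ((y[i] * Ei < -tol && alpha[i] < C) ||
            (y[i] * Ei > tol && alpha[i] > 0)) {
          j <- sample.int(n - 1L, 1L)
          if (j >= i) j <- j + 1L
          Ej <- sum(alpha * y * K[, j]) + b - y[j]
          ai_old <- alpha[i]; aj_old <- alpha[j]
          if (y[i] != y[j]) {
            L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
          } else {
            L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
          }
          if (L >= H) next
          eta <- 2 * K[i, j] - K[i, i] - K[j, j]
          if (eta >= 0) next
          aj <- aj_old - y[j] * (Ei - Ej) / eta
          aj <- min(H, max(L, aj))
          if (abs(aj - aj_old) < 1e-7) next
          ai <- ai_old + y[i] * y[j] * (aj_old - aj)
          b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
            y[j] * (aj - aj_old) * K[i, j]
          b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
            y[j] * (aj - aj_old) * K[j, j]
          b <- if (ai > 0 && ai < C) b1
               else if (aj > 0 && aj < C) b2
               else (b1 + b2) / 2
          alpha[i] <- ai; alpha[j] <- aj
          changed <- changed + 1L
        }
      }
      passes <- if (changed == 0L) passes + 1L else 0L
      sweeps <- sweeps + 1L
    }
  })

  sv <- alpha > 1e-8
  model <- list(kernel = kernel, degree = degree, gamma = gamma, C = C,
                tol = tol, alpha = alpha[sv], y_sv = y[sv],
                x_sv = x[sv, , drop = FALSE], b = b,
                features = d$features, training_accuracy = NA_real_)
  class(model) <- c("hp_svm", "hp_model")
  model$training_accuracy <- training_accuracy(model, train)
  model
}

#' @export
predict.hp_svm <- function(object, newdata,
                           type = c("class", "decision"), ...) {
  type <- match.arg(type)
  x <- newdata_matrix(object, newdata)
  kf <- kernel_fun(object$kernel, object$degree, object$gamma)
  f <- if (length(object$alpha) == 0L) {
    rep(object$b, nrow(x))
  } else {
    drop(kf(x, object$x_sv) %*% (object$alpha * object$y_sv)) + object$b
  }
  if (type == "decision") return(f)
  as_label(as.integer(f > 0))
}
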