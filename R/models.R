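# Shared helpers for the four classifier families. All models are S3
# objects inheriting "hp_model"; predict() maps rows of binary features to
# "positive"/"negative", with decision ties resolved to the negative
# (majority) class throughout.

feature_cols <- function(data) {
  grep("^f[0-9]+$", names(data), value = TRUE)
}

# numeric matrix of feature bits + 0/1 label vector (positive = 1)
design <- function(data) {
  cols <- feature_cols(data)
  if (length(cols) == 0L) stop("no feature columns (f1, f2, ...) found",
                               call. = FALSE)
  x <- as.matrix(data[cols])
  storage.mode(x) <- "double"
  if (!all(x %in% c(0, 1))) stop("feature values must be 0/1", call. = FALSE)
  y <- NULL
  if ("label" %in% names(data)) {
    if (!all(data$label %in% c("positive", "negative"))) {
      stop("labels must be 'positive' or 'negative'", call. = FALSE)
    }
    y <- as.integer(data$label == "positive")
  }
  list(x = x, y = y, features = cols)
}

as_label <- function(bit) ifelse(bit == 1L, "positive", "negative")

newdata_matrix <- function(object, newdata) {
  if (is.matrix(newdata)) {
    x <- newdata
  } else {
    missing <- setdiff(object$features, names(newdata))
    if (length(missing)) {
      stop("newdata lacks feature columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x <- as.matrix(newdata[object$features])
  }
  storage.mode(x) <- "double"
  x
}

#' Serialize a fitted classifier to JSON
#'
#' Uses a type-preserving serialization so a reloaded model reproduces every
#' prediction bit-for-bit.
#'
#' @param model A fitted \code{hp_model}.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "hp_model"))
  js <- jsonlite::serializeJSON(model)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_to_json
#' @param json JSON string or path to a file written by [model_to_json()].
#' @export
model_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  model <- jsonlite::unserializeJSON(json)
  stopifnot(inherits(model, "hp_model"))
  model
}

#' @export
print.hp_model <- function(x, ...) {
  cat(sprintf("<%s> features: %s | training accuracy: %.4f\n",
              class(x)[1], paste(x$features, collapse = ","),
              x$training_accuracy))
  invisible(x)
}

training_accuracy <- function(model, data) {
  mean(stats::predict(model, data) == data$label)
}
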