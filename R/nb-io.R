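nb_model_format_version <- 1L

#' Save or load a naive Bayes model as JSON
#'
#' The JSON document records the format version, the attribute subset, the
#' class priors, both parameter tables and the smoothing pseudocount, at
#' full floating-point precision so that `read_nb_model(write_nb_model(m))`
#' reproduces `m` exactly.
#'
#' @param model An [nb_model()].
#' @param path File path.
#' @return `write_nb_model()` returns `path` invisibly; `read_nb_model()`
#'   returns the model.
#' @export
write_nb_model <- function(model, path) {
  doc <- list(
    version = nb_model_format_version,
    subset = model$subset,
    prior = as.list(model$prior),
    continuous = model$continuous,
    categorical = model$categorical,
    alpha = model$alpha,
    sd_floor = model$sd_floor
  )
  if (!is.null(model$n_train)) doc$n_train <- as.list(model$n_train)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_nb_model
#' @export
read_nb_model <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) {
      abort(paste0("not a readable model file: ", conditionMessage(e)),
            class = "rc_model_io_error")
    }
  )
  if (is.null(doc$version) || doc$version != nb_model_format_version) {
    abort(paste0("unsupported model format version: ",
                 doc$version %||% "<missing>",
                 " (expected ", nb_model_format_version, ")"),
          class = "rc_model_io_error")
  }
  as_param_tbl <- function(x, cols) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0) {
      return(NULL)
    }
    as_tibble(x)[, cols]
  }
  m <- nb_model(
    subset = unlist(doc$subset),
    prior = c(negative = doc$prior$negative, positive = doc$prior$positive),
    continuous = as_param_tbl(doc$continuous, c("attribute", "class", "mean", "sd")),
    categorical = as_param_tbl(doc$categorical,
                               c("attribute", "class", "category", "prob")),
    alpha = doc$alpha,
    sd_floor = doc$sd_floor
  )
  if (!is.null(doc$n_train)) {
    m$n_train <- c(negative = as.integer(doc$n_train$negative),
                   positive = as.integer(doc$n_train$positive))
  }
  m
}
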