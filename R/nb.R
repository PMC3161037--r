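#' Construct a mixed-type naive Bayes model
#'
#' A naive Bayes model over a set of patient attributes F = \{F1 ... Fn\}
#' scoring the posterior probability of negative rechallenge.  Continuous
#' attributes carry per-class Gaussian parameters (mean, SD in native
#' units); categorical and binary attributes carry per-class probability
#' tables.  Usually built by [nb_fit()] or [published_model()]; the
#' constructor is exported so models can be assembled from published
#' distribution tables.
#'
#' @param subset Character vector of attribute names the model uses.
#' @param prior Named numeric `c(negative = , positive = )`, summing to 1,
#'   both strictly inside (0, 1).
#' @param continuous Tibble with columns `attribute`, `class`, `mean`, `sd`
#'   (one row per continuous attribute per class).
#' @param categorical Tibble with columns `attribute`, `class`, `category`,
#'   `prob`; per attribute per class the probabilities must sum to 1
#'   (within 1e-9).
#' @param alpha Additive smoothing pseudocount recorded at fit time.
#' @param sd_floor Lower bound applied to every Gaussian SD.
#'
#' @return An object of class `nb_model`.
#' @export
nb_model <- function(subset, prior, continuous = NULL, categorical = NULL,
                     alpha = 0, sd_floor = 1e-6) {
  empty_cont <- tibble(attribute = character(), class = character(),
                       mean = numeric(), sd = numeric())
  empty_cat <- tibble(attribute = character(), class = character(),
                      category = character(), prob = numeric())
  m <- structure(
    list(
      subset = as.character(subset),
      prior = prior,
      continuous = if (is.null(continuous)) empty_cont else as_tibble(continuous),
      categorical = if (is.null(categorical)) empty_cat else as_tibble(categorical),
      alpha = alpha,
      sd_floor = sd_floor
    ),
    class = "nb_model"
  )
  validate_nb_model(m)
}

validate_nb_model <- function(m) {
  p <- m$prior
  if (!all(rc_classes() %in% names(p))) {
    abort("prior must be named with classes `negative` and `positive`",
          class = "rc_model_error")
  }
  p <- p[rc_classes()]
  if (abs(sum(p) - 1) > 1e-9 || any(p <= 0) || any(p >= 1)) {
    abort("class priors must lie in (0,1) and sum to 1", class = "rc_model_error")
  }
  m$prior <- p
  if (nrow(m$continuous) && any(m$continuous$sd <= 0)) {
    abort("every Gaussian sd must be > 0", class = "rc_model_error")
  }
  if (nrow(m$categorical)) {
    sums <- dplyr::summarise(
      dplyr::group_by(m$categorical, .data$attribute, .data$class),
      total = sum(.data$prob), .groups = "drop"
    )
    if (any(abs(sums$total - 1) > 1e-9)) {
      bad <- sums[abs(sums$total - 1) > 1e-9, ]
      abort(paste0("categorical table does not sum to 1 for: ",
                   paste(unique(bad$attribute), collapse = ", ")),
            class = "rc_model_error")
    }
    if (any(m$categorical$prob < 0)) {
      abort("categorical probabilities must be non-negative",
            class = "rc_model_error")
    }
  }
  dup <- intersect(unique(m$continuous$attribute), unique(m$categorical$attribute))
  if (length(dup)) {
    abort(paste0("attribute(s) parameterised as both continuous and categorical: ",
                 paste(dup, collapse = ", ")), class = "rc_model_error")
  }
  params <- union(unique(m$continuous$attribute), unique(m$categorical$attribute))
  if (!setequal(params, m$subset)) {
    abort("model parameters must cover exactly the attribute subset",
          class = "rc_model_error")
  }
  m
}

#' Fit a naive Bayes model on training records
#'
#' Class priors are the empirical class frequencies.  Continuous attributes
#' get per-class sample mean and sample SD (n - 1 denominator), ignoring
#' missing values.  Categorical attributes get per-class category
#' frequencies with additive smoothing `alpha` over the schema's full
#' category list (so categories unseen in training still receive
#' probability mass when `alpha > 0`).
#'
#' @param data Labelled training records (a cohort tibble); rows with a
#'   missing `rechallenge_status` are dropped.
#' @param subset Character vector of attribute names to use (non-empty).
#' @param schema An [attribute_schema()]; supplies each attribute's kind and
#'   category list.
#' @param alpha Additive smoothing pseudocount (default 0, matching exact
#'   zero class-conditional proportions; use 1 for Laplace smoothing).
#' @param sd_floor Minimum Gaussian SD, guarding zero-variance attributes.
#'
#' @return An [nb_model()].
#' @examples
#' cohort <- generate_cohort(published_spec(), seed = 1)
#' fit <- nb_fit(cohort, subset = c("age", "albumin"))
#' glance(fit)
#' @export
nb_fit <- function(data, subset, schema = default_schema(), alpha = 0,
                   sd_floor = 1e-6) {
  if (length(subset) == 0) {
    abort("attribute subset must be non-empty", class = "rc_fit_error")
  }
  if (alpha < 0) abort("alpha must be non-negative", class = "rc_fit_error")
  data <- as_tibble(data)
  lab <- data[[rc_label_col()]]
  if (is.null(lab)) abort("training data must be labelled", class = "rc_fit_error")
  keep <- !is.na(lab)
  data <- data[keep, , drop = FALSE]
  lab <- lab[keep]
  n_by <- vapply(rc_classes(), function(cl) sum(lab == cl), integer(1))
  if (any(n_by == 0)) {
    abort(paste0("class absent from training data: ",
                 paste(rc_classes()[n_by == 0], collapse = ", ")),
          class = "rc_fit_error")
  }
  prior <- n_by / sum(n_by)

  cont <- list()
  cat_ <- list()
  for (nm in subset) {
    sp <- schema_spec(schema, nm)
    x <- data[[nm]]
    if (is.null(x)) {
      abort(paste0("attribute `", nm, "` not present in training data"),
            class = "rc_fit_error")
    }
    for (cl in rc_classes()) {
      xi <- x[lab == cl]
      if (sp$kind == "continuous") {
        xi <- xi[!is.na(xi)]
        if (length(xi) == 0) {
          abort(paste0("continuous attribute `", nm,
                       "` entirely missing within class ", cl),
                class = "rc_fit_error")
        }
        s <- if (length(xi) > 1) sd(xi) else 0
        cont[[length(cont) + 1]] <- tibble(
          attribute = nm, class = cl, mean = mean(xi),
          sd = max(s, sd_floor)
        )
      } else {
        xi <- as.character(xi)
        xi <- xi[!is.na(xi)]
        k <- length(sp$categories)
        n_obs <- length(xi)
        if (n_obs == 0 && alpha == 0) {
          abort(paste0("categorical attribute `", nm,
                       "` entirely missing within class ", cl,
                       " and alpha = 0"),
                class = "rc_fit_error")
        }
        counts <- vapply(sp$categories, function(cg) sum(xi == cg), numeric(1),
                         USE.NAMES = FALSE)
        cat_[[length(cat_) + 1]] <- tibble(
          attribute = nm, class = cl, category = sp$categories,
          prob = (counts + alpha) / (n_obs + alpha * k)
        )
      }
    }
  }
  m <- nb_model(
    subset = subset, prior = prior,
    continuous = if (length(cont)) dplyr::bind_rows(cont) else NULL,
    categorical = if (length(cat_)) dplyr::bind_rows(cat_) else NULL,
    alpha = alpha, sd_floor = sd_floor
  )
  m$n_train <- n_by
  m
}

#' Class-conditional log-likelihood of records
#'
#' Sum over the model's attributes of the log Gaussian density (continuous)
#' or log class-conditional category probability (categorical) at each
#' record's value.  Missing values contribute zero — the attribute's factor
#' is skipped.  Continuous densities can exceed 1, so individual terms may
#' be positive; a zero category probability yields `-Inf`.
#'
#' @param model An [nb_model()].
#' @param data Records to score (cohort tibble).
#' @param class `"negative"` or `"positive"`.
#' @return Numeric vector of log-likelihoods, one per row.
#' @export
nb_log_likelihood <- function(model, data, class) {
  class <- match.arg(class, rc_classes())
  data <- as_tibble(data)
  n <- nrow(data)
  ll <- numeric(n)
  cont <- model$continuous[model$continuous$class == class, ]
  for (i in seq_len(nrow(cont))) {
    x <- data[[cont$attribute[i]]]
    if (is.null(x)) {
      x <- rep(NA_real_, n)
    }
    term <- dnorm(as.numeric(x), cont$mean[i], cont$sd[i], log = TRUE)
    term[is.na(term)] <- 0
    ll <- ll + term
  }
  cats <- model$categorical[model$categorical$class == class, ]
  for (nm in unique(cats$attribute)) {
    tab <- cats[cats$attribute == nm, ]
    x <- data[[nm]]
    if (is.null(x)) x <- rep(NA_character_, n)
    p <- tab$prob[match(as.character(x), tab$category)]
    term <- log(p)
    term[is.na(x)] <- 0
    ll <- ll + term
  }
  ll
}

#' Posterior probability of negative rechallenge
#'
#' Computes, for each record, P(negative rechallenge | attributes) under the
#' conditional-independence assumption:
#' prior_neg * L_neg / (prior_neg * L_neg + prior_pos * L_pos), evaluated
#' stably in log space.  When both class likelihoods vanish (or every model
#' attribute is missing) no evidence is available and the prior is returned
#' with a warning.
#'
#' @inheritParams nb_log_likelihood
#' @return Numeric vector of posterior probabilities in \[0, 1\].
#' @export
posterior_negative <- function(model, data) {
  res <- nb_score_impl(model, data)
  if (any(res$degenerate)) {
    warn(paste0(sum(res$degenerate),
                " record(s) carried no usable evidence; prior returned"))
  }
  res$posterior
}

nb_score_impl <- function(model, data) {
  data <- as_tibble(data)
  a <- log(model$prior[["negative"]]) + nb_log_likelihood(model, data, "negative")
  b <- log(model$prior[["positive"]]) + nb_log_likelihood(model, data, "positive")
  both_dead <- is.infinite(a) & a < 0 & is.infinite(b) & b < 0
  post <- exp(a - log_sum_exp(a, b))
  post[both_dead] <- model$prior[["negative"]]

  present <- rep(FALSE, nrow(data))
  for (nm in model$subset) {
    x <- data[[nm]]
    if (!is.null(x)) present <- present | !is.na(x)
  }
  list(posterior = unname(post), degenerate = unname(both_dead | !present))
}

#' Score and classify records
#'
#' `predict()` on an `nb_model` returns either the posterior probabilities
#' (`type = "prob"`) or the predicted class at a decision threshold
#' (`type = "class"`): a record is called *negative* rechallenge exactly
#' when its posterior-negative score strictly exceeds the threshold.  A
#' score equal to the threshold is classified positive — the conservative
#' tie rule, which avoids recommending rechallenge on a boundary score.
#'
#' @param object An [nb_model()].
#' @param newdata Records to score.
#' @param threshold Decision threshold in \[0, 1\] (used for
#'   `type = "class"`).  Low thresholds favour sensitivity (curative
#'   intent); high thresholds favour specificity (palliative intent).
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return For `"class"`, a character vector of `"negative"`/`"positive"`;
#'   for `"prob"`, a tibble with columns `posterior_negative`,
#'   `posterior_positive` and `degenerate` (no usable evidence; prior
#'   returned).
#' @export
predict.nb_model <- function(object, newdata, threshold = 0.5,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  res <- nb_score_impl(object, newdata)
  if (type == "prob") {
    return(tibble(posterior_negative = res$posterior,
                  posterior_positive = 1 - res$posterior,
                  degenerate = res$degenerate))
  }
  if (threshold < 0 || threshold > 1) {
    abort("threshold must lie in [0, 1]", class = "rc_predict_error")
  }
  ifelse(res$posterior > threshold, "negative", "positive")
}

#' @export
print.nb_model <- function(x, ...) {
  cat("<nb_model> naive Bayes rechallenge model\n")
  cat("  attributes: ", length(x$subset), " (",
      paste(utils::head(x$subset, 8), collapse = ", "),
      if (length(x$subset) > 8) ", ..." else "", ")\n", sep = "")
  cat(sprintf("  prior: P(negative) = %.4f, P(positive) = %.4f\n",
              x$prior[["negative"]], x$prior[["positive"]]))
  cat("  smoothing alpha:", x$alpha, "\n")
  invisible(x)
}

#' Tidy a naive Bayes model into one row per parameter
#'
#' @param x An [nb_model()].
#' @param ... Unused.
#' @return A tibble with columns `attribute`, `kind`, `class`, `mean`,
#'   `sd`, `category`, `prob` (Gaussian rows leave `category`/`prob` `NA`
#'   and vice versa).
#' @method tidy nb_model
#' @export
tidy.nb_model <- function(x, ...) {
  cont <- dplyr::mutate(x$continuous, kind = "continuous",
                        category = NA_character_, prob = NA_real_)
  cats <- dplyr::mutate(x$categorical, kind = "categorical",
                        mean = NA_real_, sd = NA_real_)
  out <- dplyr::bind_rows(cont, cats)
  out[, c("attribute", "kind", "class", "mean", "sd", "category", "prob")]
}

#' One-row model summary
#'
#' @param x An [nb_model()].
#' @param ... Unused.
#' @return A tibble with the number of attributes, the class priors and the
#'   smoothing pseudocount.
#' @method glance nb_model
#' @export
glance.nb_model <- function(x, ...) {
  tibble(
    n_attributes = length(x$subset),
    prior_negative = x$prior[["negative"]],
    prior_positive = x$prior[["positive"]],
    alpha = x$alpha
  )
}
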