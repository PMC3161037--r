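# ROC conventions used throughout: the detection target is NEGATIVE
# rechallenge (the model scores P(negative rechallenge)), so sensitivity is
# the proportion of true negative-rechallenge cases called negative, and
# specificity the proportion of true positive-rechallenge cases called
# positive.  This direction is fixed, not configurable, to avoid silent
# axis flips in clinical reports.

check_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- !labels %in% rc_classes()
  if (any(bad)) {
    abort("labels must be `negative` or `positive`", class = "rc_eval_error")
  }
  labels
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC curve of posterior-negative scores, with
#' negative rechallenge as the detection target.  Tied scores receive half
#' credit, so the result equals the Mann-Whitney concordance: the fraction
#' of (negative, positive) pairs in which the negative-rechallenge case
#' scores strictly higher, counting ties as 1/2.
#'
#' @param scores Numeric scores (higher = more likely negative rechallenge).
#' @param labels True outcomes, `"negative"` / `"positive"`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pts <- roc_curve(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1).  Each row gives the operating point when
#'   records scoring strictly above `threshold` are called negative
#'   rechallenge.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length", class = "rc_eval_error")
  }
  if (anyNA(scores)) abort("scores must not be missing", class = "rc_eval_error")
  n_neg <- sum(labels == "negative")
  n_pos <- sum(labels == "positive")
  if (n_neg == 0 || n_pos == 0) {
    abort("AUC undefined: both outcome classes must be present",
          class = "rc_eval_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  is_target <- labels[ord] == "negative"
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp <- cumsum(is_target)
  fp <- cumsum(!is_target)
  last <- which(c(grp[-1] != grp[-length(grp)], TRUE))
  tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n_pos),
    tpr = c(0, tp[last] / n_neg)
  )
}

#' Sensitivity and specificity of predicted rechallenge outcomes
#'
#' Sensitivity: proportion of true negative-rechallenge patients predicted
#' negative.  Specificity: proportion of true positive-rechallenge patients
#' predicted positive.  Both are exact rational counts over the class sizes.
#'
#' @param predictions Predicted outcomes, `"negative"` / `"positive"`.
#' @param labels True outcomes.
#' @return A one-row tibble with columns `sensitivity`, `specificity`,
#'   `tp`, `fp`, `tn`, `fn` (negative rechallenge is the detection target,
#'   so `tp` counts correctly-called negative-rechallenge cases).
#' @export
sens_spec <- function(predictions, labels) {
  predictions <- check_labels(predictions)
  labels <- check_labels(labels)
  if (length(predictions) != length(labels) || length(labels) == 0) {
    abort("predictions and labels must be non-empty and of equal length",
          class = "rc_eval_error")
  }
  tp <- sum(predictions == "negative" & labels == "negative")
  fn <- sum(predictions == "positive" & labels == "negative")
  tn <- sum(predictions == "positive" & labels == "positive")
  fp <- sum(predictions == "negative" & labels == "positive")
  if (tp + fn == 0) {
    abort("sensitivity undefined: no true negative-rechallenge cases",
          class = "rc_eval_error")
  }
  if (tn + fp == 0) {
    abort("specificity undefined: no true positive-rechallenge cases",
          class = "rc_eval_error")
  }
  tibble(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Evaluate a model on a labelled cohort at chosen thresholds
#'
#' Scores every record with its posterior probability of negative
#' rechallenge, computes the AUC once, and derives a confusion row per
#' requested decision threshold (a record is called negative when its score
#' strictly exceeds the threshold).  The two thresholds of clinical
#' interest are the defaults: 0.01 (curative intent — do not deprive
#' patients of a useful drug) and 0.8 (palliative intent — avoid repeat
#' serious ADRs).
#'
#' @param data Labelled cohort tibble.
#' @param model An [nb_model()].
#' @param thresholds Numeric vector of decision thresholds in \[0, 1\].
#' @return A `performance_report`: list with elements `auc`, `roc` (tibble
#'   of ROC points), `per_threshold` (tibble with threshold, sensitivity,
#'   specificity and confusion counts) and `n`.
#' @export
evaluate_model <- function(data, model, thresholds = c(0.01, 0.8)) {
  data <- as_tibble(data)
  lab <- data[[rc_label_col()]]
  if (is.null(lab)) abort("cohort must be labelled", class = "rc_eval_error")
  keep <- !is.na(lab)
  data <- data[keep, , drop = FALSE]
  lab <- check_labels(lab[keep])
  scores <- nb_score_impl(model, data)$posterior
  rows <- lapply(thresholds, function(t) {
    pred <- ifelse(scores > t, "negative", "positive")
    cbind(tibble(threshold = t), sens_spec(pred, lab))
  })
  structure(
    list(
      auc = roc_auc(scores, lab),
      roc = roc_curve(scores, lab),
      per_threshold = as_tibble(dplyr::bind_rows(rows)),
      scores = scores,
      labels = lab,
      n = length(lab)
    ),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report>\n")
  cat("  scores are P(negative rechallenge); a record is called negative\n")
  cat("  when its score is strictly above the threshold\n")
  cat(sprintf("  n = %d (%d negative / %d positive rechallenge), AUC = %.3f\n",
              x$n, sum(x$labels == "negative"), sum(x$labels == "positive"),
              x$auc))
  tab <- x$per_threshold
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  threshold %.3g: sensitivity %d%%, specificity %d%% (TP %d FP %d TN %d FN %d)\n",
                tab$threshold[i], round(100 * tab$sensitivity[i]),
                round(100 * tab$specificity[i]),
                tab$tp[i], tab$fp[i], tab$tn[i], tab$fn[i]))
  }
  invisible(x)
}

#' @method tidy performance_report
#' @export
tidy.performance_report <- function(x, ...) x$per_threshold

#' @method glance performance_report
#' @export
glance.performance_report <- function(x, ...) {
  tibble(auc = x$auc, n = x$n,
         n_negative = sum(x$labels == "negative"),
         n_positive = sum(x$labels == "positive"))
}

#' Plot the ROC curve of a performance report
#'
#' @param object A `performance_report` from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot performance_report
#' @export
autoplot.performance_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity (positive rechallenge called negative)",
      y = "sensitivity (negative rechallenge detected)",
      title = sprintf("ROC, AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Write a performance report to disk
#'
#' @param report A `performance_report`.
#' @param path Output path.
#' @param format `"json"` for the full report or `"tsv"` for the ROC points.
#' @return `path`, invisibly.
#' @export
write_performance_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(report$roc, path, progress = FALSE)
  } else {
    doc <- list(
      scoring = "P(negative rechallenge); score > threshold => predicted negative",
      auc = report$auc,
      n = report$n,
      per_threshold = report$per_threshold,
      roc = report$roc
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  invisible(path)
}
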