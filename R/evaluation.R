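#' Confusion matrix at a probability threshold
#'
#' CI (label 1) is the positive class; a sample is predicted CI when its
#' probability is at least `threshold`.
#'
#' @param probs predicted CI probabilities
#' @param labels binary labels (0 = CU, 1 = CI)
#' @param threshold decision threshold in `[0, 1]` (default 0.5)
#' @return an object of class `confusion_matrix` with counts `tp`, `fp`,
#'   `tn`, `fn`
#' @export
confusion <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0L) stop("cannot build a confusion matrix from empty input")
  if (length(probs) != length(labels)) {
    stop("probs and labels must have the same length")
  }
  pred <- as.integer(probs >= threshold)
  y <- as.integer(labels)
  structure(
    list(tp = sum(pred == 1L & y == 1L),
         fp = sum(pred == 1L & y == 0L),
         tn = sum(pred == 0L & y == 0L),
         fn = sum(pred == 0L & y == 1L)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half: computed from midranks as
#' `(sum of positive ranks - n1 (n1 + 1) / 2) / (n1 * n0)`.
#'
#' @param scores numeric scores (higher = more CI-like); any strictly
#'   monotone transform gives the same AUC
#' @param labels binary labels; both classes must be present
#' @return AUC in `[0, 1]`, or `NA` if only one class is present
#' @export
auc_rank <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Six-metric classification report
#'
#' The evaluation panel for one (node, condition) cell: balanced accuracy,
#' precision, sensitivity, specificity, F1 and AUC, with CI as the positive
#' class. Ratios with zero denominators are reported as `NA` and named in the
#' `undefined` field rather than silently coerced to 0. Balanced accuracy is
#' exactly the mean of sensitivity and specificity; F1 is the harmonic mean
#' of precision and sensitivity.
#'
#' @param probs predicted CI probabilities
#' @param labels binary labels (0 = CU, 1 = CI)
#' @param threshold decision threshold (default 0.5)
#' @param node,condition,scenario optional tags recorded in the report
#' @return an object of class `metrics_report`
#' @export
classification_metrics <- function(probs, labels, threshold = 0.5,
                                   node = NA_character_,
                                   condition = NA_character_,
                                   scenario = NA_character_) {
  cm <- confusion(probs, labels, threshold)
  sensitivity <- safe_ratio(cm$tp, cm$tp + cm$fn)
  specificity <- safe_ratio(cm$tn, cm$tn + cm$fp)
  precision <- safe_ratio(cm$tp, cm$tp + cm$fp)
  bal_acc <- if (is.na(sensitivity) || is.na(specificity)) NA_real_ else
    (sensitivity + specificity) / 2
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            (precision + sensitivity) == 0) NA_real_ else
    2 * precision * sensitivity / (precision + sensitivity)
  auc <- auc_rank(probs, labels)

  metrics <- c(balanced_accuracy = bal_acc, precision = precision,
               sensitivity = sensitivity, specificity = specificity,
               f1 = f1, auc = auc)
  structure(
    c(as.list(metrics),
      list(confusion = cm,
           undefined = names(metrics)[is.na(metrics)],
           node = node, condition = condition, scenario = scenario)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  tags <- paste(stats::na.omit(c(x$scenario, x$condition, x$node)),
                collapse = " / ")
  if (nzchar(tags)) cat("<metrics_report>", tags, "\n") else
    cat("<metrics_report>\n")
  vals <- unlist(x[c("balanced_accuracy", "precision", "sensitivity",
                     "specificity", "f1", "auc")])
  print(round(vals, 2))
  invisible(x)
}

#' Flatten metric reports into a Table-style data frame
#'
#' @param reports a list of `metrics_report` objects
#' @return data.frame with tags, the six metrics (full precision), and
#'   confusion-matrix counts
#' @export
metrics_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(
      scenario = r$scenario, condition = r$condition, node = r$node,
      balanced_accuracy = r$balanced_accuracy, precision = r$precision,
      sensitivity = r$sensitivity, specificity = r$specificity,
      f1 = r$f1, auc = r$auc,
      tp = r$confusion$tp, fp = r$confusion$fp,
      tn = r$confusion$tn, fn = r$confusion$fn,
      row.names = NULL
    )
  }))
}

#' Evaluate a model on a node's test set
#'
#' @param params trained `model_params`
#' @param test a [feature_table()] test set
#' @param scaler the standardizer to apply before the forward pass (the one
#'   fitted on the training data of the node that standardizes this model's
#'   inputs)
#' @param threshold decision threshold
#' @param ... tags passed to [classification_metrics()]
#' @return a `metrics_report`
#' @export
evaluate_model <- function(params, test, scaler = NULL, threshold = 0.5, ...) {
  probs <- predict_proba(params, test, scaler = scaler)
  classification_metrics(probs, test$labels, threshold = threshold, ...)
}
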