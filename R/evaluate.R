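# Confusion counts and accuracy metrics. Per-class accuracy follows the
# one-vs-rest form (TP+TN)/(TP+FP+TN+FN); the overall metrics are reported
# both sample-weighted (micro) and as the class mean of recalls (macro),
# since published "average accuracy" figures are ambiguous between the two.

#' Confusion counts from predictions and labels
#'
#' @param predictions,labels Integer class vectors in `1..n_classes`.
#' @param n_classes Number of classes `K`.
#' @return A `confusion_counts` object: `table` (K x K matrix, rows =
#'   truth, columns = prediction), per-class `tp`/`fp`/`tn`/`fn` vectors
#'   and `n_total`.
#' @export
confusion_matrix <- function(predictions, labels, n_classes) {
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  if (length(predictions) != length(labels) || length(labels) == 0L) {
    abort_validation("predictions and labels must be equal-length, non-empty")
  }
  if (any(c(predictions, labels) < 1L) || any(c(predictions, labels) > n_classes)) {
    abort_validation("class indices must lie in 1..%d", n_classes)
  }
  tab <- matrix(0L, n_classes, n_classes,
                dimnames = list(truth = seq_len(n_classes),
                                prediction = seq_len(n_classes)))
  for (i in seq_along(labels)) {
    tab[labels[i], predictions[i]] <- tab[labels[i], predictions[i]] + 1L
  }
  tp <- diag(tab)
  fn <- rowSums(tab) - tp
  fp <- colSums(tab) - tp
  n <- length(labels)
  tn <- n - tp - fn - fp
  structure(
    list(table = tab, tp = tp, fp = fp, tn = tn, fn = fn, n_total = n),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> n = %d\n", x$n_total))
  print(x$table)
  invisible(x)
}

#' @method tidy confusion_counts
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(
    class = seq_along(x$tp),
    tp = as.integer(unname(x$tp)), fp = as.integer(unname(x$fp)),
    tn = as.integer(unname(x$tn)), fn = as.integer(unname(x$fn)),
    ovr_accuracy = unname((x$tp + x$tn) / x$n_total),
    recall = unname(ifelse(x$tp + x$fn > 0, x$tp / (x$tp + x$fn), NA_real_))
  )
}

#' Accuracy metrics from confusion counts
#'
#' Computes, for every class, the one-vs-rest accuracy
#' `(TP + TN) / (TP + FP + TN + FN)` together with the overall micro
#' accuracy (fraction of correct predictions, i.e. sample-weighted) and
#' macro accuracy (unweighted mean of per-class recalls).
#'
#' @param counts A [confusion_matrix()] result.
#' @return List with `micro`, `macro` and the per-class tibble
#'   `per_class`.
#' @export
evaluate_accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n_total < 1L) abort_validation("empty confusion counts")
  per_class <- tidy(counts)
  list(
    micro = sum(counts$tp) / counts$n_total,
    macro = mean(per_class$recall, na.rm = TRUE),
    per_class = per_class
  )
}

#' Evaluate a fitted model on a dataset split
#'
#' @param fit An `fpgcn_fit`.
#' @param data A `gait_dataset`.
#' @return List with `micro`, `macro`, `per_class`, `confusion` and `n`.
#' @export
evaluate_model <- function(fit, data) {
  preds <- predict(fit, data, type = "class")
  cm <- confusion_matrix(preds, data$class_id, fit$model$config$n_classes)
  acc <- evaluate_accuracy(cm)
  c(acc, list(confusion = cm, n = cm$n_total))
}
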