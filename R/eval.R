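# Evaluation metrics -----------------------------------------------------------

#' Confusion matrix
#'
#' @param truth Integer labels 1..k (rows).
#' @param pred Integer predictions 1..k (columns).
#' @param k Number of classes.
#' @return `k x k` integer matrix; entry (i, j) counts samples of true class i
#'   predicted as class j.
#' @export
confusion_matrix <- function(truth, pred, k = max(truth, pred)) {
  m <- matrix(0L, k, k)
  for (i in seq_along(truth)) {
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  }
  m
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return `2 * precision * recall / (precision + recall)` (0 when both are 0).
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Precision is TP / (TP + FP) over each predicted column, recall
#' TP / (TP + FN) over each true row. Classes never predicted get precision 0
#' with a warning.
#'
#' @param confusion `k x k` matrix, rows true, columns predicted.
#' @return Tibble with columns `class`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(confusion) {
  k <- nrow(confusion)
  tp <- diag(confusion)
  pred_tot <- colSums(confusion)
  true_tot <- rowSums(confusion)
  if (any(pred_tot == 0)) {
    warning("class(es) with no predicted positives: precision reported as 0",
            call. = FALSE)
  }
  precision <- ifelse(pred_tot == 0, 0, tp / pred_tot)
  recall <- ifelse(true_tot == 0, 0, tp / true_tot)
  tibble::tibble(class = seq_len(k), precision = precision, recall = recall,
                 f1 = f1_score(precision, recall))
}

#' Evaluate a model on a labelled dataset
#'
#' Argmax prediction per image, confusion matrix, accuracy and per-class
#' precision/recall/F1.
#'
#' @param fit A `seednet_fit` (or any list with a `$model`), or a
#'   `seednet_model`.
#' @param dataset List with `images` and `labels`.
#' @param batch_size Evaluation minibatch size.
#' @return An `eval_report`: list with `confusion`, `accuracy`, `per_class`
#'   (tibble), `n`.
#' @export
evaluate_model <- function(fit, dataset, batch_size = 32L) {
  model <- if (inherits(fit, "seednet_model")) fit else fit$model
  n <- length(dataset$images)
  stopifnot(n >= 1L)
  labels <- as.integer(dataset$labels)
  k <- model$cfg$num_classes
  preds <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- images_to_batch(dataset$images[idx])
    logits <- model_forward(model, xb, training = FALSE)$logits
    preds[idx] <- apply(logits, 2, which.max)
  }
  conf <- confusion_matrix(labels, preds, k)
  structure(list(confusion = conf,
                 accuracy = sum(diag(conf)) / n,
                 per_class = suppressWarnings(classification_metrics(conf)),
                 n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy %.3f\n", x$n, x$accuracy))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 macro_f1 = mean(x$per_class$f1))
}

#' Write an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @param extra Optional named list echoed into the JSON (configuration, fold
#'   assignments, seeds).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, extra = list()) {
  obj <- c(list(n = report$n, accuracy = report$accuracy,
                confusion = report$confusion,
                per_class = report$per_class),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
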