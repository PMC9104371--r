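#' Build a 3x3 confusion matrix (rows predicted, columns real)
#'
#' Orientation follows the reference study's tables: rows are the predicted
#' class, columns the real class, in the order negative, neutral, positive.
#'
#' @param predicted,real character vectors over the three class labels.
#' @return A `confusion_matrix3`: 3x3 integer matrix with dimnames
#'   `predicted` x `real`.
#' @export
confusion_matrix <- function(predicted, real) {
  stopifnot(length(predicted) == length(real))
  assert_class_labels(predicted, "predicted label")
  assert_class_labels(real, "real label")
  cm <- table(factor(predicted, levels = SENTIMENT_CLASSES),
              factor(real, levels = SENTIMENT_CLASSES))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(predicted = SENTIMENT_CLASSES,
                               real = SENTIMENT_CLASSES))
  structure(cm, class = c("confusion_matrix3", "matrix", "array"))
}

as_cm3 <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == c(3, 3)), all(cm >= 0))
  cm
}

#' Overall 3-class accuracy of a confusion matrix, in percent
#'
#' @param cm a 3x3 confusion matrix (rows predicted, columns real).
#' @return `100 * trace / total`.
#' @export
accuracy <- function(cm) {
  cm <- as_cm3(cm)
  if (sum(cm) == 0) stop("accuracy undefined for an empty matrix",
                         call. = FALSE)
  100 * sum(diag(cm)) / sum(cm)
}

#' Weighted one-vs-all metric suite
#'
#' Collapses the 3x3 matrix, per class, into a 2x2 table of that class
#' versus the rest and computes one-vs-all accuracy (TP+TN)/N, precision
#' TP/(TP+FP), recall TP/(TP+FN) and F1; each per-class value is weighted by
#' the class support (real-class count) over N and summed. Support-weighted
#' recall equals trace/total by construction, so `weighted_recall` always
#' equals `accuracy`. A class that is never predicted gets precision 0 with
#' a warning. All reported values are percents in full precision; use
#' `print()` for two-decimal display.
#'
#' @param cm a 3x3 confusion matrix (rows predicted, columns real).
#' @return A `metric_report`: list with `accuracy`, `weighted_accuracy`,
#'   `weighted_precision`, `weighted_recall`, `weighted_f1`, and a
#'   `per_class` tibble of the 2x2 collapses.
#' @export
weighted_one_vs_all <- function(cm) {
  cm <- as_cm3(cm)
  N <- sum(cm)
  if (N == 0) stop("metrics undefined for an empty matrix", call. = FALSE)
  per <- lapply(seq_len(3), function(c) {
    TP <- cm[c, c]
    FP <- sum(cm[c, ]) - TP
    FN <- sum(cm[, c]) - TP
    TN <- N - TP - FP - FN
    if (TP + FP == 0) {
      warning(sprintf("class '%s' never predicted; precision set to 0",
                      SENTIMENT_CLASSES[c]), call. = FALSE)
      prec <- 0
    } else prec <- TP / (TP + FP)
    rec <- if (TP + FN > 0) TP / (TP + FN) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = SENTIMENT_CLASSES[c], tp = TP, fp = FP, fn = FN,
                   tn = TN, support = TP + FN, accuracy = 100 * (TP + TN) / N,
                   precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1)
  })
  per <- do.call(rbind, per)
  w <- per$support / N
  structure(list(
    accuracy = 100 * sum(diag(cm)) / N,
    weighted_accuracy = sum(w * per$accuracy),
    weighted_precision = sum(w * per$precision),
    weighted_recall = sum(w * per$recall),
    weighted_f1 = sum(w * per$f1),
    per_class = per, n = N), class = "metric_report")
}

#' List misclassified testimonies by confusion cell
#'
#' @param testimonies tibble with columns `id`, `text`, `gold`.
#' @param predicted character vector, one prediction per testimony.
#' @return A `misclassification_report` tibble of the off-diagonal items
#'   (`id`, `text`, `gold`, `predicted`), sorted by (gold, predicted) cell.
#' @export
misclassification_report <- function(testimonies, predicted) {
  stopifnot(is.data.frame(testimonies),
            all(c("id", "text", "gold") %in% names(testimonies)))
  if (nrow(testimonies) != length(predicted)) {
    stop("one prediction per testimony required", call. = FALSE)
  }
  assert_class_labels(predicted, "predicted label")
  assert_class_labels(testimonies$gold, "gold label")
  out <- tibble::tibble(id = testimonies$id, text = testimonies$text,
                        gold = testimonies$gold, predicted = predicted)
  out <- out[out$gold != out$predicted, ]
  out <- out[order(out$gold, out$predicted), ]
  structure(out, class = c("misclassification_report", class(out)))
}

#' @export
print.confusion_matrix3 <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) sprintf("%.2f%%", round_half_up(v, 2))
  cat("<metric_report> n =", x$n, "\n")
  cat("  accuracy          ", fmt(x$accuracy), "\n")
  cat("  weighted accuracy ", fmt(x$weighted_accuracy), "\n")
  cat("  weighted precision", fmt(x$weighted_precision), "\n")
  cat("  weighted recall   ", fmt(x$weighted_recall), "\n")
  cat("  weighted F1       ", fmt(x$weighted_f1), "\n")
  invisible(x)
}

#' Write a confusion matrix or metric report to disk
#'
#' Matrices go to TSV (rows predicted, columns real); reports to JSON with
#' full-precision values.
#'
#' @param cm a `confusion_matrix3`.
#' @param report a `metric_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confusion_tsv <- function(cm, path) {
  utils::write.table(as.data.frame(unclass(cm)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_confusion_tsv
#' @export
write_metrics_json <- function(report, path) {
  out <- report[c("accuracy", "weighted_accuracy", "weighted_precision",
                  "weighted_recall", "weighted_f1", "n")]
  out$per_class <- report$per_class
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
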