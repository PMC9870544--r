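#' Build a confusion matrix
#'
#' Rows are gold labels, columns are predictions, over the union of observed
#' labels and `labels`.
#'
#' @param gold,pred character/factor vectors of equal length.
#' @param labels optional class order; defaults to the sorted union.
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(gold, pred, labels = NULL) {
  stopifnot(length(gold) == length(pred))
  if (length(gold) == 0L) stop("no observations to tabulate")
  if (is.null(labels)) labels <- sort(union(unique(gold), unique(pred)))
  cm <- table(factor(gold, levels = labels), factor(pred, levels = labels))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("gold", "predicted")
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Per-class and macro-averaged classification metrics
#'
#' Precision TP/(TP+FP), recall TP/(TP+FN) and their harmonic mean (F1) per
#' class, plus accuracy (trace/total) and the macro averages -- unweighted
#' arithmetic means of the per-class values. Classes with a zero denominator
#' score 0 with a warning. Full precision is kept internally; use
#' [round_half_up()] for 2-decimal display.
#'
#' @param cm a [confusion_matrix()].
#' @return An object of class `metrics_report`: `per_class` data.frame
#'   (class, support, precision, recall, f1), `accuracy`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `n`.
#' @export
classification_metrics <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stop("cm must be square")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  zero <- colsum == 0 | rowsum == 0
  if (any(zero)) {
    warning("zero-support or never-predicted class(es): ",
            paste(rownames(cm)[zero], collapse = ", "),
            " -- affected metrics set to 0")
  }
  precision <- ifelse(colsum > 0, tp / colsum, 0)
  recall <- ifelse(rowsum > 0, tp / rowsum, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    per_class = data.frame(class = rownames(cm), support = as.integer(rowsum),
                           precision = unname(precision),
                           recall = unname(recall), f1 = unname(f1),
                           stringsAsFactors = FALSE),
    accuracy = sum(tp) / total,
    macro_precision = macro_average(precision),
    macro_recall = macro_average(recall),
    macro_f1 = macro_average(f1),
    n = total
  ), class = "metrics_report")
}

#' Macro average
#'
#' Unweighted arithmetic mean of a per-class metric.
#'
#' @param x numeric vector of per-class values.
#' @return Numeric scalar.
#' @export
#' @examples
#' macro_average(c(0.70, 0.86, 0.93))
macro_average <- function(x) {
  if (length(x) == 0L) stop("macro_average() needs at least one value")
  mean(x)
}

#' Accuracy of a confusion matrix
#' @param cm a [confusion_matrix()].
#' @return trace/total.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Round half away from zero
#'
#' Display rounding for reported metrics (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.825, 2)  # 0.83
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Evaluate predictions against a gold standard
#'
#' Joins by `id` and computes the full metrics report. Sentiment evaluation is
#' 3-class (positive/neutral/negative); emotion evaluation is 9-class (eight
#' emotions plus neutral).
#'
#' @param gold data.frame with columns `id`, `label`.
#' @param pred data.frame with columns `id`, `label`.
#' @param labels optional class order.
#' @return A `metrics_report`.
#' @export
evaluate_predictions <- function(gold, pred, labels = NULL) {
  stopifnot(all(c("id", "label") %in% names(gold)),
            all(c("id", "label") %in% names(pred)))
  merged <- merge(gold, pred, by = "id", suffixes = c("_gold", "_pred"))
  if (nrow(merged) == 0L) stop("no overlapping ids between gold and predictions")
  classification_metrics(
    confusion_matrix(merged$label_gold, merged$label_pred, labels))
}

#' @export
print.metrics_report <- function(x, digits = 2L, ...) {
  pc <- x$per_class
  pc$precision <- round_half_up(pc$precision, digits)
  pc$recall <- round_half_up(pc$recall, digits)
  pc$f1 <- round_half_up(pc$f1, digits)
  cat(sprintf("Classification metrics (n = %d)\n", x$n))
  print(pc, row.names = FALSE)
  cat(sprintf("accuracy: %.*f  macro P/R/F1: %.*f / %.*f / %.*f\n",
              digits, round_half_up(x$accuracy, digits),
              digits, round_half_up(x$macro_precision, digits),
              digits, round_half_up(x$macro_recall, digits),
              digits, round_half_up(x$macro_f1, digits)))
  invisible(x)
}

#' Bundled benchmark tables
#'
#' Worked-example tables from a published Weibo COVID-19 emotion study,
#' shipped as plain CSVs: per-class evaluation metrics (sentiment and
#' emotion), corpus emotion distributions (overall and by user group) and the
#' printed sentiment rollup percentages. Used by the test suite and the
#' acceptance script as fixed reference inputs.
#'
#' @param name one of "sentiment_metrics", "emotion_metrics",
#'   "distribution_overall", "distribution_groups", "sentiment_rollups".
#' @return A data.frame.
#' @export
benchmark_table <- function(name = c("sentiment_metrics", "emotion_metrics",
                                     "distribution_overall",
                                     "distribution_groups",
                                     "sentiment_rollups")) {
  name <- match.arg(name)
  path <- system.file("extdata", "benchmarks", paste0(name, ".csv"),
                      package = "microemo")
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
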