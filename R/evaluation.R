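#' Confusion matrix for a two-class prediction
#'
#' Class 1 (e.g. the seedless cultivar) is the positive class throughout:
#' TP = class1 predicted class1, TN = class2 predicted class2, FP = class2
#' predicted class1, FN = class1 predicted class2 (the standard 2x2
#' convention).
#'
#' @param truth A [label_table()], or a factor/character vector named by
#'   sample id.
#' @param predicted Factor/character vector of predicted labels, named by
#'   sample id (order may differ from `truth`).
#' @return A list of class `confusion_matrix` with counts `tp`, `tn`, `fp`,
#'   `fn` and `total`.
#' @export
confusion <- function(truth, predicted) {
  if (is.data.frame(truth)) truth <- stats::setNames(as.character(truth$label),
                                                     truth$sample_id)
  truth <- stats::setNames(as.character(truth), names(truth))
  predicted <- stats::setNames(as.character(predicted), names(predicted))
  if (length(truth) == 0L) stop("empty input")
  if (!is.null(names(truth)) && !is.null(names(predicted))) {
    if (!setequal(names(truth), names(predicted)))
      stop("truth and prediction cover different sample ids")
    predicted <- predicted[names(truth)]
  } else if (length(truth) != length(predicted)) {
    stop("truth and prediction lengths differ")
  }
  structure(list(tp = sum(truth == "class1" & predicted == "class1"),
                 tn = sum(truth == "class2" & predicted == "class2"),
                 fp = sum(truth == "class2" & predicted == "class1"),
                 fn = sum(truth == "class1" & predicted == "class2"),
                 total = length(truth)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("class1", "class2"),
                              predicted = c("class1", "class2")))
  print(m)
  invisible(x)
}

#' Write a confusion matrix as CSV
#' @param cm A [confusion()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  utils::write.csv(data.frame(truth = c("class1", "class1", "class2", "class2"),
                              predicted = c("class1", "class2", "class1", "class2"),
                              count = c(cm$tp, cm$fn, cm$fp, cm$tn)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, per-class precision, recall and F1:
#' \deqn{Accuracy = (TP+TN)/(TP+FP+TN+FN)}
#' \deqn{Precision_1 = TP/(TP+FP), \quad Precision_2 = TN/(TN+FN)}
#' \deqn{Recall_1 = TP/(TP+FN), \quad Recall_2 = TN/(TN+FP)}
#' \deqn{F1_c = 2 \cdot Precision_c \cdot Recall_c / (Precision_c + Recall_c)}
#' Ratios with a zero denominator are returned as `NaN` with a warning.
#'
#' @param cm A [confusion()] result (or a list with `tp`, `tn`, `fp`, `fn`).
#' @return A list of class `metrics_report` with `accuracy`, `precision_1`,
#'   `precision_2`, `recall_1`, `recall_2`, `f1_1`, `f1_2` and the counts.
#' @export
metrics <- function(cm) {
  counts <- c(cm$tp, cm$tn, cm$fp, cm$fn)
  if (any(counts < 0)) stop("negative confusion counts")
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  p1 <- ratio(cm$tp, cm$tp + cm$fp, "precision_1")
  p2 <- ratio(cm$tn, cm$tn + cm$fn, "precision_2")
  r1 <- ratio(cm$tp, cm$tp + cm$fn, "recall_1")
  r2 <- ratio(cm$tn, cm$tn + cm$fp, "recall_2")
  f1 <- function(p, r) if (is.nan(p) || is.nan(r) || p + r == 0) {
    warning("F1 undefined", call. = FALSE); NaN
  } else 2 * p * r / (p + r)
  structure(list(accuracy = (cm$tp + cm$tn) / total,
                 precision_1 = p1, precision_2 = p2,
                 recall_1 = r1, recall_2 = r2,
                 f1_1 = suppressWarnings(f1(p1, r1)),
                 f1_2 = suppressWarnings(f1(p2, r2)),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("accuracy: %.*f\n", digits, x$accuracy))
  cat(sprintf("class1: precision %.*f, recall %.*f, F1 %.*f\n", digits,
              x$precision_1, digits, x$recall_1, digits, x$f1_1))
  cat(sprintf("class2: precision %.*f, recall %.*f, F1 %.*f\n", digits,
              x$precision_2, digits, x$recall_2, digits, x$f1_2))
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report A [metrics()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(
    c(report[c("accuracy", "precision_1", "precision_2", "recall_1",
               "recall_2", "f1_1", "f1_2")],
      list(confusion = report$confusion[c("tp", "tn", "fp", "fn")])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
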