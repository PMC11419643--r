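# Confusion-matrix construction and the metric suite ------------------------

#' One-vs-rest confusion counts
#'
#' Counts TP/FP/TN/FN for the stated positive class; the full K x K
#' cross-tabulation is attached as attribute `"table"`.
#'
#' @param predicted,actual equal-length vectors of class codes.
#' @param positive_class the code treated as positive.
#' @return object of class `confusion_counts` with fields `TP`, `FP`, `TN`,
#'   `FN` (their sum equals the number of scored records).
#' @export
confusion_counts <- function(predicted, actual, positive_class = 1) {
  if (length(predicted) != length(actual))
    stop_arg("predicted and actual must have equal length")
  p <- predicted == positive_class
  a <- actual == positive_class
  lv <- sort(unique(c(predicted, actual)))
  out <- structure(list(TP = sum(p & a), FP = sum(p & !a),
                        TN = sum(!p & !a), FN = sum(!p & a),
                        positive_class = positive_class),
                   class = "confusion_counts")
  attr(out, "table") <- table(factor(actual, lv), factor(predicted, lv),
                              dnn = c("actual", "predicted"))
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> positive = %s: TP %d FP %d TN %d FN %d\n",
              format(x$positive_class), x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

safe_ratio <- function(num, den) {
  if (den == 0) structure(0, undefined = TRUE) else num / den
}

#' Metric suite from confusion counts
#'
#' Precision TP/(TP+FP); recall and sensitivity TP/(TP+FN); specificity
#' TN/(TN+FP); F-measure 2PR/(P+R); accuracy (TP+TN)/total; NPV TN/(TN+FN);
#' MCC (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A metric with
#' zero denominator is reported as 0 and flagged in `undefined`.
#'
#' @param counts a [confusion_counts()] object (or list with TP/FP/TN/FN).
#' @return object of class `metrics_report` with the eight metrics, the
#'   counts and an `undefined` character vector.
#' @export
metrics_report <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (any(c(TP, FP, TN, FN) < 0)) stop_arg("counts must be nonnegative")
  total <- TP + FP + TN + FN
  if (total == 0) stop_arg("no scored records")
  precision <- safe_ratio(TP, TP + FP)
  recall <- safe_ratio(TP, TP + FN)
  specificity <- safe_ratio(TN, TN + FP)
  f_den <- as.numeric(precision) + as.numeric(recall)
  f_measure <- if (f_den == 0) structure(0, undefined = TRUE)
               else 2 * as.numeric(precision) * as.numeric(recall) / f_den
  npv <- safe_ratio(TN, TN + FN)
  mcc_den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  mcc <- if (mcc_den == 0) structure(0, undefined = TRUE)
         else (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  vals <- list(precision = precision, recall = recall,
               sensitivity = recall, specificity = specificity,
               f_measure = f_measure,
               accuracy = (TP + TN) / total, npv = npv, mcc = mcc)
  undefined <- names(vals)[vapply(vals, function(v)
    isTRUE(attr(v, "undefined")), TRUE)]
  vals <- lapply(vals, as.numeric)
  structure(c(vals, list(counts = counts, undefined = undefined)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  nm <- c("precision", "recall", "sensitivity", "specificity",
          "f_measure", "accuracy", "npv", "mcc")
  for (m in nm)
    cat(sprintf("  %-12s %.4f%s\n", m, x[[m]],
                if (m %in% x$undefined) " (undefined: 0/0)" else ""))
  invisible(x)
}

#' Macro- or micro-averaged multi-class metrics
#'
#' One-vs-rest metrics per class, averaged. Macro averages the per-class
#' metric values; micro pools the counts first.
#'
#' @param predicted,actual class code vectors.
#' @param average `"macro"` or `"micro"`.
#' @return a `metrics_report` (averaged), with per-class reports in
#'   `per_class`.
#' @export
multiclass_metrics <- function(predicted, actual,
                               average = c("macro", "micro")) {
  average <- match.arg(average)
  classes <- sort(unique(c(predicted, actual)))
  reports <- lapply(classes, function(cl)
    metrics_report(confusion_counts(predicted, actual, cl)))
  names(reports) <- as.character(classes)
  nm <- c("precision", "recall", "sensitivity", "specificity",
          "f_measure", "accuracy", "npv", "mcc")
  if (average == "macro") {
    vals <- lapply(nm, function(m)
      mean(vapply(reports, function(r) r[[m]], 0)))
  } else {
    pooled <- list(TP = sum(vapply(reports, function(r) r$counts$TP, 0)),
                   FP = sum(vapply(reports, function(r) r$counts$FP, 0)),
                   TN = sum(vapply(reports, function(r) r$counts$TN, 0)),
                   FN = sum(vapply(reports, function(r) r$counts$FN, 0)))
    mr <- metrics_report(pooled)
    vals <- lapply(nm, function(m) mr[[m]])
  }
  names(vals) <- nm
  structure(c(vals, list(average = average, per_class = reports)),
            class = "metrics_report")
}
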