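#' Classification metrics from confusion counts
#'
#' Evaluates accuracy, sensitivity, specificity, F1 and the Matthews
#' correlation coefficient from TP/TN/FP/FN, plus balanced accuracy
#' (mean of sensitivity and specificity):
#' \deqn{Accuracy=(TP+TN)/(TP+TN+FP+FN)}
#' \deqn{Sensitivity=TP/(TP+FN),\; Specificity=TN/(TN+FP)}
#' \deqn{F1=TP/(TP+\tfrac12(FP+FN))}
#' \deqn{MCC=(TP\cdot TN-FP\cdot FN)/\sqrt{(TP+FN)(TP+FP)(TN+FN)(TN+FP)}}
#' A metric whose denominator is zero is reported as 0 and named in the
#' `zero_denominator` field, so downstream tables never contain holes.
#'
#' @param tp,tn,fp,fn Nonnegative integer counts (alternatively pass a
#'   single list/vector with named elements to `tp`).
#' @return List of class `metrics_report`: accuracy, sensitivity,
#'   specificity, f1, mcc, balanced_accuracy, counts, zero_denominator.
#' @export
classification_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && (is.list(tp) || length(tp) == 4L)) {
    cc <- tp
    tp <- cc[["tp"]]; tn <- cc[["tn"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(counts) == 0) stop("all-zero confusion counts", call. = FALSE)
  zero <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { zero <<- c(zero, name); return(0) }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fn, tn + fp)))
  out <- list(
    accuracy = (tp + tn) / sum(counts),
    sensitivity = sens,
    specificity = spec,
    f1 = safe(tp, tp + (fp + fn) / 2, "f1"),
    mcc = safe(tp * tn - fp * fn, mcc_den, "mcc"),
    balanced_accuracy = (sens + spec) / 2,
    counts = counts,
    zero_denominator = zero)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f | sensitivity %.4f | specificity %.4f | ",
                     "F1 %.4f | MCC %.4f | balanced acc %.4f\n"),
              x$accuracy, x$sensitivity, x$specificity, x$f1, x$mcc,
              x$balanced_accuracy))
  if (length(x$zero_denominator))
    cat("zero-denominator metrics reported as 0:",
        paste(x$zero_denominator, collapse = ", "), "\n")
  invisible(x)
}

#' Confusion counts from labels and hard predictions
#' @param labels,predicted 0/1 vectors of equal length.
#' @return Named list tp/tn/fp/fn.
#' @export
confusion_counts <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted))
  list(tp = sum(labels == 1 & predicted == 1),
       tn = sum(labels == 0 & predicted == 0),
       fp = sum(labels == 0 & predicted == 1),
       fn = sum(labels == 1 & predicted == 0))
}

#' ROC and precision-recall curves with tie-aware areas
#'
#' Thresholds sweep the distinct score values in descending order (tied
#' scores collapse into a single operating point). AUROC is the trapezoid
#' area under the ROC curve — equal to the probability that a random positive
#' outranks a random negative, with half-credit for ties; AUPR is the
#' step-interpolated area \eqn{\sum_k (R_k - R_{k-1}) P_k}.
#'
#' @param labels 0/1 vector (both classes must be present).
#' @param scores Numeric scores, higher = more positive.
#' @return List of class `roc_pr`: `roc` (data.frame fpr/tpr/threshold),
#'   `pr` (data.frame recall/precision/threshold), `auroc`, `aupr`.
#' @export
roc_pr <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0)
    stop("both classes must be present", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[ends]; fp <- cumsum(1 - y)[ends]
  tpr <- tp / pos; fpr <- fp / neg
  precision <- tp / (tp + fp); recall <- tpr
  fpr0 <- c(0, fpr); tpr0 <- c(0, tpr)
  auroc <- sum(diff(fpr0) * (tpr0[-length(tpr0)] + tpr0[-1]) / 2)
  aupr <- sum(diff(c(0, recall)) * precision)
  structure(list(
    roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                     threshold = c(Inf, s[ends])),
    pr = data.frame(recall = recall, precision = precision,
                    threshold = s[ends]),
    auroc = auroc, aupr = aupr), class = "roc_pr")
}

#' @export
print.roc_pr <- function(x, ...) {
  cat(sprintf("AUROC %.4f | AUPR %.4f (%d operating points)\n",
              x$auroc, x$aupr, nrow(x$roc) - 1L))
  invisible(x)
}
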