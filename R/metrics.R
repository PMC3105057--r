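#' Confusion counts for binary AFP classification
#'
#' Container for the four cells of a binary confusion matrix, with the AFP
#' class treated as positive.
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return An object of class `confusion_counts`.
#' @examples
#' confusion_counts(tp = 44, tn = 3736, fp = 26, fn = 0)
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  if (sum(counts) < 1) {
    stop("confusion counts must total at least 1")
  }
  structure(as.list(as.numeric(counts)), names = names(counts),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Tally confusion counts from labels and predictions
#'
#' @param truth,predicted Character vectors over `{"AFP", "NONAFP"}`, equal
#'   length, aligned element-wise.
#' @return A `confusion_counts` object.
#' @export
tally_confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  ok <- c("AFP", "NONAFP")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("labels must be 'AFP' or 'NONAFP'")
  }
  confusion_counts(tp = sum(truth == "AFP" & predicted == "AFP"),
                   tn = sum(truth == "NONAFP" & predicted == "NONAFP"),
                   fp = sum(truth == "NONAFP" & predicted == "AFP"),
                   fn = sum(truth == "AFP" & predicted == "NONAFP"))
}

#' Per-class identification accuracy Q_i
#'
#' Q_i = 100 * c_i / n_i where c_i is the number of correctly identified
#' sequences of class i and n_i the number of sequences in that class.
#'
#' @param counts A `confusion_counts` object.
#' @param class `"AFP"` (sensitivity) or `"NONAFP"` (specificity).
#' @return Percentage in \[0, 100\].
#' @export
class_accuracy <- function(counts, class = c("AFP", "NONAFP")) {
  class <- match.arg(class)
  stopifnot(inherits(counts, "confusion_counts"))
  n_i <- if (class == "AFP") counts$tp + counts$fn else counts$tn + counts$fp
  if (n_i == 0) {
    stop("class accuracy undefined: no sequences of class ", class)
  }
  c_i <- if (class == "AFP") counts$tp else counts$tn
  100 * c_i / n_i
}

#' Overall identification accuracy
#'
#' Equals `100 * (TP + TN) / N`, which is identically the class-frequency
#' weighted sum of the per-class accuracies, `sum_i f_i * Q_i` with
#' `f_i = n_i / N`.
#'
#' @inheritParams class_accuracy
#' @return Percentage in \[0, 100\].
#' @export
overall_accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$tn + counts$fp + counts$fn
  100 * (counts$tp + counts$tn) / n
}

#' Positive-class (AFP) precision
#'
#' @inheritParams class_accuracy
#' @return Percentage `100 * TP / (TP + FP)`.
#' @export
precision <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fp == 0) {
    stop("precision undefined: no positive predictions")
  }
  100 * counts$tp / (counts$tp + counts$fp)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; 1 is a perfect
#' correlation, 0 random, -1 inverse.  When any factor of the denominator is
#' zero the coefficient is defined as 0 (standard convention).
#'
#' @inheritParams class_accuracy
#' @return A value in \[-1, 1\].
#' @examples
#' mcc(confusion_counts(44, 3736, 26, 0))  # 0.790
#' @export
mcc <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  den <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(den == 0)) {
    return(0)
  }
  # product of four counts can exceed 2^53 only for astronomically large n;
  # work in logs to stay exact to double precision regardless
  (tp * tn - fp * fn) / exp(sum(log(den)) / 2)
}

#' Table-style evaluation report
#'
#' Summarizes a confusion matrix as the rows conventionally reported for
#' AFP identification benchmarks: per-class accuracy, precision, overall
#' accuracy, MCC and the raw counts.
#'
#' @inheritParams class_accuracy
#' @return A data.frame with columns `metric` and `value`; percentages are
#'   rounded to one decimal for display, MCC to three.
#' @export
evaluation_report <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  data.frame(
    metric = c("AFP accuracy (%)", "AFP precision (%)",
               "Overall accuracy (%)", "MCC", "TP", "TN", "FP", "FN"),
    value = c(round(class_accuracy(counts, "AFP"), 1),
              round(precision(counts), 1),
              round(overall_accuracy(counts), 1),
              round(mcc(counts), 3),
              counts$tp, counts$tn, counts$fp, counts$fn),
    stringsAsFactors = FALSE
  )
}
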