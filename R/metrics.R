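#' Confusion counts for binary predictions
#'
#' @param predicted,actual 0/1 vectors of equal length; 1 is the positive
#'   (case) class.
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual),
            all(predicted %in% c(0, 1)), all(actual %in% c(0, 1)))
  structure(list(
    TP = sum(predicted == 1 & actual == 1),
    FP = sum(predicted == 1 & actual == 0),
    TN = sum(predicted == 0 & actual == 0),
    FN = sum(predicted == 0 & actual == 1)
  ), class = "confusion_counts")
}

#' Classification accuracy
#'
#' `(TP + TN) / n_total`, the proportion of correctly classified samples.
#'
#' @param counts A [confusion_counts()].
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  if (n == 0) stop("no samples: accuracy undefined", call. = FALSE)
  (counts$TP + counts$TN) / n
}

#' True-positive rate (sensitivity)
#'
#' `TP / (TP + FN)`. When no positives exist the rate is undefined and
#' `NA_real_` is returned rather than 0.
#'
#' @param counts A [confusion_counts()].
#' @return TPR in `[0, 1]`, or `NA_real_`.
#' @export
tpr <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) return(NA_real_)
  counts$TP / d
}

#' False-positive rate
#'
#' `FP / (FP + TN)`, the rate at which negatives are called positive — the
#' x-axis of the ROC curve. Undefined (NA) when there are no negatives.
#'
#' @param counts A [confusion_counts()].
#' @return FPR in `[0, 1]`, or `NA_real_`.
#' @export
fpr <- function(counts) {
  d <- counts$FP + counts$TN
  if (d == 0) return(NA_real_)
  counts$FP / d
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores in descending order;
#' tied scores move the operating point in one step. Points start at (0, 0)
#' and end at (1, 1), with non-decreasing FPR.
#'
#' @param scores Numeric scores, larger = more case-like.
#' @param y 0/1 labels; both classes must be present.
#' @return A `roc_curve` data.frame with columns `fpr`, `tpr`, `threshold`,
#'   and attribute `auc` (see [auc_trapezoid()]).
#' @export
roc_curve <- function(scores, y) {
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) stop("both classes must be present for a ROC curve", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  cum_tp <- cumsum(yy == 1)
  cum_fp <- cumsum(yy == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)  # one point per distinct threshold
  out <- data.frame(
    fpr = c(0, cum_fp[last] / N),
    tpr = c(0, cum_tp[last] / P),
    threshold = c(Inf, s[last])
  )
  class(out) <- c("roc_curve", "data.frame")
  attr(out, "auc") <- sum(diff(out$fpr) * (out$tpr[-1] + out$tpr[-nrow(out)]) / 2)
  out
}

#' Area under a ROC curve by the trapezoid rule
#'
#' Equals the probability that a random case outscores a random control,
#' with ties counted one half.
#'
#' @param curve A [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
}

#' Write ROC points to delimited text
#'
#' @param curve A [roc_curve()].
#' @param path Output path.
#' @param delimiter Field delimiter; TAB by default.
#' @return `path`, invisibly.
#' @export
write_roc <- function(curve, path, delimiter = "\t") {
  utils::write.table(as.data.frame(curve)[, c("fpr", "tpr", "threshold")],
                     path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}
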