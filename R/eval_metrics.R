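#' Root mean square error
#'
#' @param y,yhat Numeric vectors of equal length (>= 1): observed and
#'   predicted values.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat))
  if (length(y) != length(yhat) || length(y) < 1L)
    stop("y and yhat must be nonempty vectors of equal length", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation between observed and predicted values;
#' invariant under positive affine transforms of either argument. Constant
#' inputs make the statistic undefined and raise an error rather than
#' returning NA.
#'
#' @inheritParams rmse
#' @return A scalar in `[-1, 1]`.
#' @export
pearson_r <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat))
  if (length(y) != length(yhat) || length(y) < 2L)
    stop("y and yhat must have equal length >= 2", call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("correlation undefined for a constant input vector", call. = FALSE)
  stats::cor(y, yhat, method = "pearson")
}

#' Confusion-matrix counts
#'
#' @param TP,TN,FP,FN Nonnegative integer counts, at least one positive.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  stopifnot(is.numeric(v), all(is.finite(v)))
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(v) < 1) stop("at least one count must be positive", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Tabulate binary predictions into confusion counts
#'
#' @param truth,pred Logical (or 0/1) vectors of equal length.
#' @return A [confusion_counts()] object.
#' @export
confusion_from_labels <- function(truth, pred) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  if (length(truth) != length(pred) || anyNA(truth) || anyNA(pred))
    stop("truth and pred must be equal-length binary vectors without NA",
         call. = FALSE)
  confusion_counts(TP = sum(truth & pred), TN = sum(!truth & !pred),
                   FP = sum(!truth & pred), FN = sum(truth & !pred))
}

#' Accuracy, precision, recall and Matthews correlation
#'
#' The four binary classification metrics computed from confusion counts:
#' accuracy `(TP + TN) / (P + N)`, precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)` and `MCC = (TP*TN - FP*FN) /
#' sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A metric whose denominator is zero
#' is reported as `NA` (explicitly undefined), never silently as 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named list `accuracy`, `precision`, `recall`, `mcc`; MCC lies in
#'   `[-1, 1]` when defined.
#' @examples
#' classification_metrics(confusion_counts(TP = 50, TN = 40, FP = 10, FN = 0))
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  list(accuracy = div(TP + TN, TP + TN + FP + FN),
       precision = div(TP, TP + FP),
       recall = div(TP, TP + FN),
       mcc = if (mcc_den == 0) NA_real_
             else (TP * TN - FP * FN) / sqrt(mcc_den))
}

#' One-vs-rest classification metrics for multiclass labels
#'
#' Binarizes a multiclass truth/prediction pair one class at a time,
#' reports the binary metrics per class, and macro-averages precision,
#' recall and MCC over the classes where they are defined.
#'
#' @param truth,pred Vectors of class labels, equal length.
#' @return A list with `per_class` (data frame) and `macro` (named list of
#'   macro-averaged precision, recall, mcc, plus overall accuracy).
#' @export
multiclass_metrics <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length", call. = FALSE)
  classes <- sort(unique(c(truth, pred)))
  per <- do.call(rbind, lapply(classes, function(cl) {
    m <- classification_metrics(confusion_from_labels(truth == cl, pred == cl))
    data.frame(class = cl, precision = m$precision, recall = m$recall,
               mcc = m$mcc, stringsAsFactors = FALSE)
  }))
  list(per_class = per,
       macro = list(accuracy = mean(truth == pred),
                    precision = mean(per$precision, na.rm = TRUE),
                    recall = mean(per$recall, na.rm = TRUE),
                    mcc = mean(per$mcc, na.rm = TRUE)))
}
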