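# Binary confusion matrices and the seven diagnostic metrics, plus the
# single-operating-point AROC and a threshold-sweep ROC curve.

#' Binary confusion matrix
#'
#' Either tallies `truth` against `predicted` (binary tasks only) or, when
#' `tp` is given, wraps explicit counts. The positive class defaults to
#' label 1 (malignant in the breast-cancer schemas).
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive_label The label counted as positive.
#' @param tp,fn,fp,tn Explicit nonnegative counts (alternative interface;
#'   when `tp` is supplied the label vectors are ignored).
#' @return An object of class `"fln_confusion"` with fields `tp`, `fn`,
#'   `fp`, `tn`, `positive_label`.
#' @examples
#' confusion_matrix(c(1, 1, 2), c(1, 2, 2))
#' confusion_matrix(tp = 71, fn = 1, fp = 0, tn = 133)
#' @export
confusion_matrix <- function(truth = NULL, predicted = NULL,
                             positive_label = 1L,
                             tp = NULL, fn = NULL, fp = NULL, tn = NULL) {
  if (!is.null(tp)) {
    counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
    if (length(counts) != 4L || anyNA(counts) || any(counts < 0))
      stop("invalid input: tp, fn, fp, tn must all be nonnegative counts")
    return(structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                          positive_label = positive_label),
                     class = "fln_confusion"))
  }
  if (length(truth) != length(predicted))
    stop("shape error: truth and predicted must have equal length")
  classes <- unique(c(truth, predicted))
  if (length(classes) > 2L)
    stop("unsupported task: the metric suite is binary only (",
         length(classes), " classes seen)")
  pos_t <- truth == positive_label
  pos_p <- predicted == positive_label
  structure(list(tp = sum(pos_t & pos_p), fn = sum(pos_t & !pos_p),
                 fp = sum(!pos_t & pos_p), tn = sum(!pos_t & !pos_p),
                 positive_label = positive_label),
            class = "fln_confusion")
}

#' @export
print.fln_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

# ratio with the documented 0/0 rule: returns 0 and records the metric name
safe_ratio <- function(num, den, name, flags) {
  if (den == 0) {
    flags$hit <- c(flags$hit, name)
    return(0)
  }
  num / den
}

#' Seven diagnostic metrics plus single-point AROC
#'
#' Computes, from a binary confusion matrix: accuracy, precision, recall
#' (sensitivity), specificity, F-measure (harmonic mean of precision and
#' recall), G-mean (`sqrt(specificity * recall)`), the Matthews correlation
#' coefficient, and the single-operating-point AROC
#' (`(recall + specificity) / 2`). All values are on the `[0, 1]` scale
#' (MCC in `[-1, 1]`). Any ratio with a zero denominator is defined as 0
#' and the affected metric names are recorded in the report's `flagged`
#' field, so batch runs never abort.
#'
#' @param cm An [confusion_matrix()] with at least one counted sample.
#' @return An object of class `"fln_metrics"`: a list with the eight metric
#'   values and `flagged`, a character vector of zero-denominator metrics.
#' @examples
#' compute_metrics(confusion_matrix(tp = 71, fn = 1, fp = 0, tn = 133))
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "fln_confusion"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total < 1) stop("invalid input: empty confusion matrix")
  flags <- new.env()
  flags$hit <- character(0)
  accuracy <- (cm$tp + cm$tn) / total
  precision <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision", flags)
  recall <- safe_ratio(cm$tp, cm$tp + cm$fn, "recall", flags)
  specificity <- safe_ratio(cm$tn, cm$tn + cm$fp, "specificity", flags)
  f_measure <- safe_ratio(2 * precision * recall, precision + recall,
                          "f_measure", flags)
  g_mean <- sqrt(specificity * recall)
  denom <- sqrt(as.numeric(cm$tp + cm$fp) * (cm$tp + cm$fn) *
                  (cm$tn + cm$fp) * (cm$tn + cm$fn))
  mcc <- safe_ratio(as.numeric(cm$tp) * cm$tn - as.numeric(cm$fp) * cm$fn,
                    denom, "mcc", flags)
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 specificity = specificity, f_measure = f_measure,
                 g_mean = g_mean, mcc = mcc,
                 balanced_auroc = (recall + specificity) / 2,
                 flagged = flags$hit),
            class = "fln_metrics")
}

#' @export
print.fln_metrics <- function(x, digits = 5, ...) {
  v <- unlist(x[metric_names()])
  print(round(v, digits))
  if (length(x$flagged))
    cat("zero-denominator metrics set to 0:",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Canonical metric-report field names
#'
#' The eight metric names, in the order reports serialize them.
#' @return Character vector of length 8.
#' @export
metric_names <- function() {
  c("accuracy", "precision", "recall", "specificity", "f_measure",
    "g_mean", "mcc", "balanced_auroc")
}

#' @export
as.data.frame.fln_metrics <- function(x, ...) {
  as.data.frame(x[metric_names()])
}

#' Single-operating-point AROC
#'
#' The area under the ROC curve through a single (FPR, TPR) operating
#' point, which reduces to `(sensitivity + specificity) / 2`. This is the
#' AROC figure reported for a hard classifier's confusion matrix; for
#' continuous scores use [roc_curve()].
#'
#' @param cm An [confusion_matrix()].
#' @return A real in `[0, 1]`.
#' @examples
#' balanced_auroc(confusion_matrix(tp = 71, fn = 1, fp = 0, tn = 133))
#' @export
balanced_auroc <- function(cm) {
  compute_metrics(cm)$balanced_auroc
}

#' ROC curve from continuous scores
#'
#' Standard threshold sweep over the unique score values (predict positive
#' when `score >= threshold`), returning the (FPR, TPR) points anchored at
#' (0,0) and (1,1) and the trapezoidal area under the curve.
#'
#' @param scores Numeric vector of positive-class scores.
#' @param truth Label vector with exactly two observed classes.
#' @param positive_label The positive class label.
#' @return A list of class `"fln_roc"` with `points` (data frame `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, truth, positive_label = 1L) {
  if (length(scores) != length(truth))
    stop("shape error: scores and truth must have equal length")
  if (any(!is.finite(scores)))
    stop("invalid input: scores must be finite")
  pos <- truth == positive_label
  P <- sum(pos)
  N <- sum(!pos)
  if (P == 0L || N == 0L)
    stop("undefined curve: both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / N, numeric(1))
  fpr <- c(0, fpr)
  tpr <- c(0, tpr)
  if (fpr[length(fpr)] != 1 || tpr[length(tpr)] != 1) {
    fpr <- c(fpr, 1)
    tpr <- c(tpr, 1)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "fln_roc")
}

#' @export
print.fln_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.5f\n", nrow(x$points), x$auc))
  invisible(x)
}
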