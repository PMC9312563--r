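#' Rank-based AUROC
#'
#' Mann-Whitney U statistic scaled to `[0, 1]`, with half credit for tied
#' scores (midrank convention).
#'
#' @param scores Numeric score per observation, higher meaning more likely
#'   positive.
#' @param truth Logical (or coercible) indicator of the positive class.
#' @return AUROC in `[0, 1]`; `NA` with a warning if only one class is
#'   present.
#' @export
auroc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: single-class truth")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics: accuracy, Cohen's kappa, F1, AUROC
#'
#' Accuracy is the fraction correct; kappa is `(p_o - p_e) / (1 - p_e)`
#' with chance agreement from the prediction/truth marginals; F1 is the
#' harmonic precision/recall mean with the disease class as positive;
#' AUROC is computed from `scores` when given (rank-based, ties at 0.5),
#' otherwise from the 0/1 predictions.
#'
#' @param truth Vector of true class labels.
#' @param predictions Vector of predicted class labels (same label set).
#'   May be omitted when `scores` and `cutoff` are given.
#' @param scores Optional numeric scores for the positive class.
#' @param positive The positive (disease) class label.
#' @param cutoff Threshold turning scores into predictions
#'   (`score >= cutoff` is positive) when `predictions` is missing.
#' @return List of class `classifier_metrics` with `accuracy`, `kappa`,
#'   `f1`, `auroc`, `confusion` (TP/FP/FN/TN) and `n`.
#' @export
classifier_metrics <- function(truth, predictions = NULL, scores = NULL,
                               positive, cutoff = 0.5) {
  if (is.null(predictions)) {
    if (is.null(scores)) stop("need predictions or scores")
    predictions <- ifelse(scores >= cutoff, positive, paste0("non-", positive))
    truth2 <- ifelse(truth == positive, positive, paste0("non-", positive))
  } else truth2 <- as.character(truth)
  predictions <- as.character(predictions)
  if (length(predictions) != length(truth2)) stop("length mismatch")
  pos_t <- truth2 == positive
  pos_p <- predictions == positive
  tp <- sum(pos_t & pos_p); fp <- sum(!pos_t & pos_p)
  fn <- sum(pos_t & !pos_p); tn <- sum(!pos_t & !pos_p)
  n <- length(truth2)
  accuracy <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e == 1) 0 else (accuracy - p_e) / (1 - p_e)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  auc <- if (!is.null(scores)) auroc(scores, pos_t) else
    auroc(as.numeric(pos_p), pos_t)
  structure(list(accuracy = accuracy, kappa = kappa, f1 = f1, auroc = auc,
                 confusion = c(TP = tp, FP = fp, FN = fn, TN = tn), n = n),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  kappa %.4f  F1 %.4f  AUROC %s\n",
              x$accuracy, x$kappa, x$f1,
              ifelse(is.na(x$auroc), "NA", sprintf("%.4f", x$auroc))))
  cat(sprintf("confusion TP %d FP %d FN %d TN %d (n = %d)\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["FN"],
              x$confusion["TN"], x$n))
  invisible(x)
}
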