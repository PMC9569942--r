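# Classifier quality metrics in the form the recurrence models are
# reported: sensitivity, specificity, Cohen's kappa, precision, and the
# ROC curve with its AUC, plus a per-model metrics table for train/test
# splits.

#' Confusion-matrix metrics for binary predictions
#'
#' Sensitivity Se = TP/(TP+FN), specificity Sp = TN/(TN+FP), precision
#' Pr = TP/(TP+FP), and Cohen's kappa Ka = (p_o - p_e)/(1 - p_e) with
#' chance agreement p_e from the marginal products. A zero denominator
#' yields NaN with a warning, never a silent 0.
#'
#' @param predicted,truth binary labels ("BCR"/"BRF", or 0/1 with 1 =
#'   positive), equal length.
#' @param positive label treated as positive (default "BCR").
#' @return list with `TP`, `FP`, `TN`, `FN`, `Se`, `Sp`, `Pr`, `Ka`.
#' @export
confusion_metrics <- function(predicted, truth, positive = "BCR") {
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  as_pos <- function(v) {
    if (is.numeric(v)) v == 1 else as.character(v) == positive
  }
  p <- as_pos(predicted); t <- as_pos(truth)
  TP <- sum(p & t); FP <- sum(p & !t); TN <- sum(!p & !t); FN <- sum(!p & t)
  n <- length(t)
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    num / den
  }
  p_o <- (TP + TN) / n
  p_e <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / n^2
  ka <- if (p_e == 1) {
    warning("kappa undefined: chance agreement is 1")
    NaN
  } else (p_o - p_e) / (1 - p_e)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       Se = rate(TP, TP + FN, "sensitivity"),
       Sp = rate(TN, TN + FP, "specificity"),
       Pr = rate(TP, TP + FP, "precision"),
       Ka = ka)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (descending); the curve starts at
#' (0, 0) and ends at (1, 1), and the AUC is computed by the trapezoid
#' rule, so tied scores contribute one half (equivalently
#' AUC = U / (n_pos * n_neg)).
#'
#' @param scores numeric scores (higher = more positive).
#' @param truth binary labels (see [confusion_metrics()]).
#' @param positive positive label (default "BCR").
#' @return object of class `roc_curve`: list with `curve`
#'   (data.frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive = "BCR") {
  t <- if (is.numeric(truth)) truth == 1 else as.character(truth) == positive
  n_pos <- sum(t); n_neg <- sum(!t)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one positive and one negative label")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) sum(scores >= s & t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(s) sum(scores >= s & !t) / n_neg, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1) {
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve with", nrow(x$curve), "points; AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Youden-optimal threshold of a ROC curve
#'
#' The threshold maximizing TPR - FPR (reported for transparency next to
#' the default 0.5 cut).
#'
#' @param roc a [roc_auc()] result.
#' @return the optimal threshold (numeric).
#' @export
youden_threshold <- function(roc) {
  j <- roc$curve$tpr - roc$curve$fpr
  roc$curve$threshold[which.max(j)]
}

#' Train/test metrics row for one model
#'
#' Evaluates a trained FCNN on its training and test splits: Se, Sp, Ka, Pr
#' at the given probability threshold, and the AUC of the recurrence score,
#' laid out test/training like the published model tables.
#'
#' @param name model label.
#' @param model trained `fcnn_model`.
#' @param x_train,y_train,x_test,y_test the two splits.
#' @param threshold probability cut for hard labels (default 0.5).
#' @return one-row data.frame: `model`, `Se_test`, `Sp_test`, `Ka_test`,
#'   `Pr_test`, `AUC_test`, `Se_train`, ..., `AUC_train`.
#' @export
model_metrics_row <- function(name, model, x_train, y_train, x_test, y_test,
                              threshold = 0.5) {
  side <- function(x, y, suffix) {
    truth <- ifelse(coerce_labels(y) == 1, "BCR", "BRF")
    pred <- predict_class(model, x, threshold)
    cm <- confusion_metrics(pred, truth)
    auc <- roc_auc(predict_proba(model, x)[, "p_BCR"], truth)$auc
    stats::setNames(
      data.frame(cm$Se, cm$Sp, cm$Ka, cm$Pr, auc),
      paste0(c("Se_", "Sp_", "Ka_", "Pr_", "AUC_"), suffix))
  }
  cbind(data.frame(model = name, stringsAsFactors = FALSE),
        side(x_test, y_test, "test"), side(x_train, y_train, "train"))
}
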