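# Multiclass evaluation: confusion matrix, overall and per-class
# accuracy, precision / recall / F1, one-vs-rest ROC AUC, optional kappa.

#' Metrics from a confusion matrix
#'
#' Rows are truth, columns predictions. Per-class precision is
#' `TP / (TP + FP)`, recall `TP / (TP + FN)`, F1 `2PR / (P + R)` (0 when
#' `P + R` is 0 but both are defined). Metrics of a class absent from the
#' truth are NA, not 0. The one-vs-rest accuracy of class k counts both
#' true positives and true negatives for k.
#'
#' @param confusion square count matrix (rows = truth).
#' @param auc optional per-class AUC vector to carry into the report.
#' @param withKappa also compute Cohen's kappa.
#' @return a [MetricsReport-class].
#' @export
confusionMetrics <- function(confusion, auc = NULL, withKappa = FALSE) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  k <- nrow(confusion)
  if (is.null(rownames(confusion))) {
    rownames(confusion) <- colnames(confusion) <-
      if (k == 3L) intensityLevels() else paste0("C", seq_len(k))
  }
  total <- sum(confusion)
  acc <- sum(diag(confusion)) / total
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- total - tp - fn - fp
  present <- rowSums(confusion) > 0
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(present, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall),
               ifelse(precision + recall > 0,
                      2 * precision * recall / (precision + recall), 0),
               NA_real_)
  ovr <- ifelse(present, (tp + tn) / total, NA_real_)
  precision[!present] <- NA_real_
  f1[!present] <- NA_real_
  per <- data.frame(class = rownames(confusion),
                    recall = as.numeric(recall),
                    ovrAccuracy = as.numeric(ovr),
                    precision = as.numeric(precision),
                    f1 = as.numeric(f1),
                    auc = if (is.null(auc)) NA_real_ else as.numeric(auc))
  kappa <- NA_real_
  if (withKappa) {
    po <- acc
    pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
    kappa <- if (abs(1 - pe) < 1e-12) 1 else (po - pe) / (1 - pe)
  }
  new("MetricsReport", confusion = confusion, accuracy = acc,
      perClass = per, macroF1 = mean(per$f1, na.rm = TRUE), kappa = kappa)
}

#' One-vs-rest ROC AUC by trapezoidal integration
#'
#' Builds the ROC curve by sweeping the decision threshold over the
#' scores (ties handled by grouping equal scores) and integrates TPR over
#' FPR with the trapezoidal rule.
#'
#' @param scores numeric vector of predicted scores for the positive class.
#' @param positive logical vector, TRUE where the case is positive.
#' @return AUC in `[0, 1]`; NA when either class is absent.
#' @export
rocAuc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positive[ord]
  # cumulative counts at each distinct threshold
  tps <- cumsum(p)
  fps <- cumsum(!p)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tps[keep] / nPos)
  fpr <- c(0, fps[keep] / nNeg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Evaluate a model on a test set
#'
#' Runs the classifier in evaluation mode and derives the full metric
#' suite: 3x3 confusion matrix, overall accuracy, per-class recall (the
#' usual reading of per-class accuracy), one-vs-rest accuracy, precision,
#' F1, and one-vs-rest ROC AUC from the predicted probabilities.
#'
#' @param model a trained [ViTBiLSTM-class].
#' @param test a nonempty [SequenceSet-class].
#' @param withKappa also compute Cohen's kappa.
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, test, withKappa = FALSE) {
  stopifnot(nObs(test) > 0L)
  res <- classify(model, test)
  truth <- factor(as.character(test@labels), levels = model@classes)
  pred <- factor(as.character(res$label), levels = model@classes)
  confusion <- unclass(table(truth = truth, predicted = pred))
  auc <- vapply(seq_along(model@classes), function(k) {
    rocAuc(res$prob[, k], truth == model@classes[k])
  }, numeric(1))
  confusionMetrics(confusion, auc = auc, withKappa = withKappa)
}

#' Write a metrics report as JSON
#'
#' @param report a [MetricsReport-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeMetrics <- function(report, path) {
  stopifnot(is(report, "MetricsReport"))
  jsonlite::write_json(
    list(accuracy = report@accuracy,
         macroF1 = report@macroF1,
         kappa = report@kappa,
         confusion = report@confusion,
         perClass = report@perClass),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
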