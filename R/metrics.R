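#' Confusion matrix from true and predicted labels
#'
#' Entry (i, j) counts items whose true class is i and predicted class j.
#' Row and column order is the supplied class order (default: the sorted
#' union of observed labels; the four-class leukocyte task uses
#' `cellClasses()`).
#'
#' @param trueLabels,predictedLabels Equal-length character vectors.
#' @param classes Class-name order for rows/columns.
#' @return C x C integer matrix with dimnames.
#' @export
confusionMatrix <- function(trueLabels, predictedLabels, classes = NULL) {
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors have different lengths", call. = FALSE)
  if (length(trueLabels) < 1L) stop("no labels supplied", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(trueLabels, predictedLabels)))
  bad <- setdiff(unique(c(trueLabels, predictedLabels)), classes)
  if (length(bad))
    stop("labels outside the class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tf <- factor(trueLabels, levels = classes)
  pf <- factor(predictedLabels, levels = classes)
  tab <- table(tf, pf)
  matrix(as.integer(tab), nrow = length(classes),
         dimnames = list(classes, classes))
}

#' Overall accuracy from a confusion matrix
#'
#' The ratio of correctly classified items (the trace) to all items.
#'
#' @param cm Confusion matrix.
#' @return Accuracy in [0, 1].
#' @export
overallAccuracy <- function(cm) {
  total <- sum(cm)
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * P * R / (P + R)`; 0 when both are 0.
#'
#' @param precision,recall Rates in [0, 1] (vectorized).
#' @return F1 in [0, 1].
#' @examples
#' f1Score(0.80, 1.00)  # 0.888..., prints as 0.89 at 2 decimals
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class precision, recall and F1
#'
#' Precision for class c is the diagonal over the column sum (fraction of
#' predictions of c that are correct); recall is the diagonal over the row
#' sum (fraction of true c correctly classified); F1 is their harmonic
#' mean. Degenerate classes (zero column or row sum) receive value 0 and an
#' `undefined` flag rather than an error.
#'
#' @param cm Confusion matrix.
#' @return data.frame: class, precision, recall, f1, undefined (logical).
#' @export
perClassPRF <- function(cm) {
  if (sum(cm) < 1) stop("empty confusion matrix", call. = FALSE)
  diagv <- diag(cm)
  colS <- colSums(cm)
  rowS <- rowSums(cm)
  precision <- ifelse(colS == 0, 0, diagv / colS)
  recall <- ifelse(rowS == 0, 0, diagv / rowS)
  data.frame(class = rownames(cm), precision = precision, recall = recall,
             f1 = f1Score(precision, recall),
             undefined = colS == 0 | rowS == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Macro-averaged precision, recall and F1
#'
#' Unweighted arithmetic means across classes; macro-F1 is the mean of the
#' per-class F1 values (not the F1 of the macro precision/recall).
#'
#' @param perClass data.frame from [perClassPRF()], or any data.frame with
#'   columns precision, recall, f1.
#' @return Named numeric vector: macroPrecision, macroRecall, macroF1.
#' @examples
#' macroScores(data.frame(precision = c(1, 1, 0.8, 1),
#'                        recall = c(1, 1, 1, 0.98),
#'                        f1 = c(1, 1, 0.89, 0.99)))
#' @export
macroScores <- function(perClass) {
  if (nrow(perClass) < 1L) stop("need >= 1 class", call. = FALSE)
  c(macroPrecision = mean(perClass$precision),
    macroRecall = mean(perClass$recall),
    macroF1 = mean(perClass$f1))
}

#' Micro-averaged F1 from a confusion matrix
#'
#' True/false positives and false negatives are summed over all classes
#' before forming precision and recall; micro-F1 is their harmonic mean.
#' For single-label multiclass problems the summed FP and FN both equal
#' total minus trace, so micro-F1 coincides with accuracy.
#'
#' @param cm Confusion matrix.
#' @return Micro-F1 in [0, 1].
#' @export
microF1 <- function(cm) {
  total <- sum(cm)
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  tp <- sum(diag(cm))
  fp <- sum(colSums(cm) - diag(cm))
  fn <- sum(rowSums(cm) - diag(cm))
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  f1Score(p, r)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p0 - pe) / (1 - pe)` where p0 is the
#' observed accuracy and pe the chance agreement
#' `sum_c rowsum(c) * colsum(c) / total^2` from the marginals. The
#' degenerate case pe = 1 (all mass in one cell of a single class) is
#' flagged: kappa is 1 when agreement is also perfect, otherwise NA with
#' `undefined = TRUE`.
#'
#' @param cm Confusion matrix.
#' @return List: kappa, p0, pe, undefined.
#' @export
cohenKappa <- function(cm) {
  total <- sum(cm)
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  p0 <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (isTRUE(all.equal(pe, 1))) {
    if (isTRUE(all.equal(p0, 1)))
      return(list(kappa = 1, p0 = p0, pe = pe, undefined = FALSE))
    return(list(kappa = NA_real_, p0 = p0, pe = pe, undefined = TRUE))
  }
  list(kappa = (p0 - pe) / (1 - pe), p0 = p0, pe = pe, undefined = FALSE)
}

#' One-vs-rest ROC curves and AUC per class
#'
#' For each class, items of that class are the positives and all others the
#' negatives; the ROC is traced over the distinct score thresholds and the
#' AUC computed by the trapezoidal rule, which (with tied scores grouped)
#' equals the Mann-Whitney concordance probability with half credit for
#' ties. Classes without both a positive and a negative item are flagged
#' undefined (AUC NA).
#'
#' @param scores N x C matrix of class scores/probabilities, columns named
#'   by class (or in `classes` order).
#' @param trueLabels Character vector of length N.
#' @param classes Class order; default the score column names.
#' @return List per class: `roc` (data.frame fpr, tpr) and `auc`.
#' @export
rocAuc <- function(scores, trueLabels, classes = colnames(scores)) {
  if (is.null(classes)) stop("scores must have named columns", call. = FALSE)
  out <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    pos <- trueLabels == cl
    s <- scores[, ci]
    if (!any(pos) || all(pos)) {
      out[[cl]] <- list(roc = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                        auc = NA_real_, undefined = TRUE)
      next
    }
    thr <- sort(unique(s), decreasing = TRUE)
    nP <- sum(pos)
    nN <- sum(!pos)
    tpr <- c(0, vapply(thr, function(t) sum(s >= t & pos) / nP, 1))
    fpr <- c(0, vapply(thr, function(t) sum(s >= t & !pos) / nN, 1))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    out[[cl]] <- list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                      undefined = FALSE)
  }
  out
}

#' Assemble the full evaluation report for a trained model
#'
#' Runs the model over the evaluation items and collects the complete
#' metric suite: confusion matrix, accuracy, per-class
#' precision/recall/F1, macro and micro averages, Cohen's kappa and
#' one-vs-rest ROC/AUC per class.
#'
#' @param model A [DenseModel-class].
#' @param data List with `x` (input tensor) and `labels` (character), e.g.
#'   from [stackImages()].
#' @return An [EvalReport-class] object.
#' @export
evaluateModel <- function(model, data) {
  if (is.null(data$labels) || all(is.na(data$labels)))
    stop("evaluation items must be labelled", call. = FALSE)
  pred <- predictModel(model, data$x)
  buildEvalReport(data$labels, pred$predicted, pred$probabilities,
                  classes = model@classNames)
}

#' @rdname evaluateModel
#' @param trueLabels,predictedLabels Character label vectors.
#' @param scores Optional N x C score matrix for ROC/AUC.
#' @param classes Class order.
#' @export
buildEvalReport <- function(trueLabels, predictedLabels, scores = NULL,
                            classes = cellClasses()) {
  cm <- confusionMatrix(trueLabels, predictedLabels, classes)
  pc <- perClassPRF(cm)
  mac <- macroScores(pc)
  kap <- cohenKappa(cm)
  roc <- list()
  auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  if (!is.null(scores)) {
    rr <- rocAuc(scores, trueLabels, classes)
    roc <- lapply(rr, `[[`, "roc")
    auc <- vapply(rr, `[[`, 1, "auc")
  }
  new("EvalReport", confusion = cm, accuracy = overallAccuracy(cm),
      perClass = pc, macroPrecision = unname(mac["macroPrecision"]),
      macroRecall = unname(mac["macroRecall"]),
      macroF1 = unname(mac["macroF1"]), microF1 = microF1(cm),
      kappa = kap$kappa, p0 = kap$p0, pe = kap$pe, roc = roc, auc = auc)
}

#' Round half-up for report display
#'
#' Display rounding for report tables (2 decimals by default); internal
#' metric values are kept at full precision.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @examples
#' roundHalfUp(0.885)  # 0.89
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (all metrics), `per_class.csv` in the conventional
#' classification-report layout (class, precision, recall, f1-score plus
#' accuracy / macro avg / weighted avg rows, 2-decimal display rounding)
#' and `confusion.csv`.
#'
#' @param report An [EvalReport-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
writeEvalReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pc <- report@perClass
  w <- rowSums(report@confusion) / sum(report@confusion)
  tab <- data.frame(
    class = c(pc$class, "accuracy", "macro avg", "weighted avg"),
    precision = roundHalfUp(c(pc$precision, NA, report@macroPrecision,
                              sum(w * pc$precision))),
    recall = roundHalfUp(c(pc$recall, NA, report@macroRecall,
                           sum(w * pc$recall))),
    f1.score = roundHalfUp(c(pc$f1, report@accuracy, report@macroF1,
                             sum(w * pc$f1))))
  utils::write.csv(tab, file.path(dir, "per_class.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report@confusion),
                   file.path(dir, "confusion.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    accuracy = report@accuracy, macroPrecision = report@macroPrecision,
    macroRecall = report@macroRecall, macroF1 = report@macroF1,
    microF1 = report@microF1, kappa = report@kappa, p0 = report@p0,
    pe = report@pe, auc = as.list(report@auc),
    perClass = pc, confusion = report@confusion),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
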