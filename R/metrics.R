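#' Multiclass confusion matrix
#'
#' Rows are true classes, columns predicted, both over the fixed 8-class
#' order (or a supplied subset).
#'
#' @param truth,pred vectors of class labels (factor/character over the
#'   tissue codes).
#' @param classes class order (default [tissue_classes()]).
#' @return An integer matrix of counts with `dimnames` truth x predicted.
#' @export
confusion <- function(truth, pred, classes = tissue_classes()) {
  if (length(truth) != length(pred))
    stop_lungtex("truth and pred must have equal length", "lungtex_input_error")
  t_f <- factor(as.character(truth), levels = classes)
  p_f <- factor(as.character(pred), levels = classes)
  cm <- table(truth = t_f, predicted = p_f)
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Row-normalized view of a confusion matrix
#' @param cm an integer confusion matrix.
#' @return Matrix of per-true-class proportions (rows sum to 1; all-zero
#'   rows stay zero).
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  sweep(cm, 1, pmax(rs, 1L), "/")
}

#' Per-class and macro-averaged classification metrics
#'
#' One-vs-rest sensitivity and specificity per class,
#' `SN = TP / (TP + FN)`, `SP = TN / (TN + FP)`, with the derived
#' geometric mean `GM = sqrt(SN * SP)` and balanced accuracy
#' `BA = (SN + SP) / 2`. Macro values are the *unweighted* arithmetic means
#' across classes, equalizing class importance under skewed test sets.
#' (The geometric mean is deliberately computed from the SN/SP rates, the
#' form every published per-class row satisfies, not from raw TP/TN
#' counts.) A class with no true samples has undefined sensitivity and
#' raises an error naming the class.
#'
#' @param cm confusion matrix from [confusion()].
#' @param classes classes to include (default: all rows of `cm`).
#' @return A `class_metrics` object: list with `per_class` (data.frame of
#'   class, SN, SP, GM, BA) and `macro` (named vector of the four macro
#'   averages).
#' @export
metrics_from_confusion <- function(cm, classes = rownames(cm)) {
  rs <- rowSums(cm)
  absent <- classes[rs[classes] == 0]
  if (length(absent) > 0)
    stop_lungtex(sprintf(
      "sensitivity undefined for class(es) with no true samples: %s",
      paste(absent, collapse = ", ")), "lungtex_metric_error")
  total <- sum(cm)
  per <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fn <- rs[cl] - tp
    fp <- sum(cm[, cl]) - tp
    tn <- total - tp - fn - fp
    sn <- tp / (tp + fn)
    sp <- tn / (tn + fp)
    data.frame(class = cl, SN = sn, SP = sp,
               GM = sqrt(sn * sp), BA = (sn + sp) / 2,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  macro <- c(SN = mean(per$SN), SP = mean(per$SP),
             GM = mean(per$GM), BA = mean(per$BA))
  structure(list(per_class = per, macro = macro), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, digits = 4, ...) {
  df <- x$per_class
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  cat("macro: ", paste(sprintf("%s %.4f", names(x$macro), x$macro),
                       collapse = "  "), "\n")
  invisible(x)
}

#' Metric identities from published operating points
#'
#' Recomputes the derived metrics GM and BA from a sensitivity/specificity
#' pair - useful for auditing printed per-class tables.
#'
#' @param sn,sp sensitivity and specificity in `[0, 1]` (vectorized).
#' @return data.frame with columns `SN`, `SP`, `GM`, `BA`.
#' @examples
#' metrics_from_rates(0.9118, 0.9907)   # GM 0.9504, BA 0.9512
#' @export
metrics_from_rates <- function(sn, sp) {
  data.frame(SN = sn, SP = sp, GM = sqrt(sn * sp), BA = (sn + sp) / 2)
}

#' Macro-averaged one-vs-rest ROC
#'
#' Builds one ROC curve per class from the (renormalized) fused class
#' scores, interpolates each true-positive rate onto a common
#' false-positive-rate grid, and averages across classes; the macro AUC is
#' the trapezoidal area of the averaged curve. Per-class curves and AUCs
#' come from the pROC package.
#'
#' @param scores `N x n_classes` score matrix (fused ensemble scores; they
#'   are renormalized to rowwise probabilities internally).
#' @param truth true class labels of the N samples.
#' @param fpr_grid common false-positive-rate grid.
#' @return A `macro_roc` object: list with `fpr`, `tpr` (macro curve),
#'   `auc` (macro AUC), `per_class_auc` (named vector).
#' @export
macro_roc <- function(scores, truth,
                      fpr_grid = seq(0, 1, by = 0.001)) {
  truth <- factor(as.character(truth), levels = tissue_classes())
  present <- levels(truth)[table(truth) > 0]
  if (length(present) < 2L)
    stop_lungtex("macro ROC needs at least two classes present",
                 "lungtex_roc_error")
  rs <- rowSums(scores)
  prob <- sweep(scores, 1, pmax(rs, 1e-12), "/")
  colnames(prob) <- tissue_classes()[seq_len(ncol(prob))]
  tprs <- matrix(NA_real_, length(fpr_grid), length(present),
                 dimnames = list(NULL, present))
  aucs <- numeric(length(present))
  names(aucs) <- present
  for (cl in present) {
    resp <- as.integer(truth == cl)
    r <- pROC::roc(response = resp, predictor = prob[, cl],
                   direction = "<", quiet = TRUE)
    fpr <- rev(1 - r$specificities)
    tpr <- rev(r$sensitivities)
    tprs[, cl] <- stats::approx(fpr, tpr, xout = fpr_grid, ties = max,
                                rule = 2)$y
    aucs[cl] <- as.numeric(pROC::auc(r))
  }
  tpr_macro <- rowMeans(tprs)
  auc_macro <- sum(diff(fpr_grid) * (head(tpr_macro, -1) + tail(tpr_macro, -1)) / 2)
  structure(list(fpr = fpr_grid, tpr = tpr_macro, auc = auc_macro,
                 per_class_auc = aucs),
            class = "macro_roc")
}

#' @export
print.macro_roc <- function(x, ...) {
  cat(sprintf("<macro_roc> macro AUC %.4f over %d classes\n",
              x$auc, length(x$per_class_auc)))
  invisible(x)
}

#' @export
plot.macro_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("Macro-averaged ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
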