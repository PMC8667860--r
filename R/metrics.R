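#' Confusion matrix for binary DBP classification
#'
#' @param tp,fp,tn,fn Non-negative integer counts: true positives, false
#'   positives, true negatives, false negatives (positive = DNA-binding).
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop_validation("confusion counts must be non-negative integers")
  }
  v <- as.integer(v)
  structure(list(tp = v[1], fp = v[2], tn = v[3], fn = v[4]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Threshold-free and thresholded classification metrics
#'
#' From a confusion matrix:
#' `ACC = (TP+TN)/(TP+TN+FP+FN) * 100`,
#' `SN = TP/(TP+FN) * 100`, `SP = TN/(TN+FP) * 100`, and Matthews
#' correlation
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FN)(TP+FP)(TN+FP))`.
#' Whenever a denominator factor is zero the affected metric follows the
#' standard convention: MCC = 0 (flagged via `mcc_degenerate`), SN/SP
#' are `NaN`-free and reported as 0.
#'
#' @param cm A [confusion_matrix()] with at least one count.
#' @return List with `acc`, `sn`, `sp` (percentages in `[0, 100]`),
#'   `mcc` in `[-1, 1]`, and logical `mcc_degenerate`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total == 0L) stop_degenerate("empty confusion matrix")
  acc <- (tp + tn) / total * 100
  sn <- if (tp + fn == 0L) 0 else tp / (tp + fn) * 100
  sp <- if (tn + fp == 0L) 0 else tn / (tn + fp) * 100
  den <- as.double(tp + fn) * (tn + fn) * (tp + fp) * (tn + fp)
  degenerate <- den == 0
  mcc <- if (degenerate) 0 else
    (as.double(tp) * tn - as.double(fp) * fn) / sqrt(den)
  list(acc = acc, sn = sn, sp = sp, mcc = mcc, mcc_degenerate = degenerate)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct scores in descending
#' order (tied scores grouped), producing an ROC that starts at (0, 0)
#' and ends at (1, 1). The AUC is the trapezoid-rule area, which equals
#' the Mann-Whitney concordance probability with ties counted one half.
#'
#' @param labels 0/1 vector (1 = positive); both classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return List with `roc` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc` in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop_validation("length mismatch")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop_validation("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- which(c(diff(s) != 0, TRUE))      # last index of each tie group
  ctp <- cumsum(y == 1L)[grp_end]
  cfp <- cumsum(y == 0L)[grp_end]
  roc <- data.frame(fpr = c(0, cfp / nn), tpr = c(0, ctp / np),
                    threshold = c(Inf, s[grp_end]))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' Full evaluation report from labels and scores
#'
#' Applies the classification threshold (default 0.5) to build the
#' confusion matrix, computes ACC/SN/SP/MCC and the ROC/AUC.
#'
#' @param labels True 0/1 labels.
#' @param scores Classifier scores in `[0, 1]`.
#' @param threshold Score at or above which a sample is called positive.
#' @return Object of class `eval_report`: the confusion matrix, the
#'   metric list, `roc` points and `auc`.
#' @export
eval_report <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  cm <- confusion_matrix(tp = sum(pred == 1L & labels == 1L),
                         fp = sum(pred == 1L & labels == 0L),
                         tn = sum(pred == 0L & labels == 0L),
                         fn = sum(pred == 0L & labels == 1L))
  met <- classification_metrics(cm)
  ra <- roc_auc(labels, scores)
  structure(list(cm = cm, acc = met$acc, sn = met$sn, sp = met$sp,
                 mcc = met$mcc, mcc_degenerate = met$mcc_degenerate,
                 roc = ra$roc, auc = ra$auc, threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("ACC %.1f%%  SN %.1f%%  SP %.1f%%  MCC %.3f  AUC %.3f\n",
              x$acc, x$sn, x$sp, x$mcc, x$auc))
  invisible(x)
}

#' Write an evaluation report as JSON (and optional ROC TSV)
#'
#' @param report An [eval_report()].
#' @param path JSON output path.
#' @param roc_path Optional path for the ROC points as TSV.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, roc_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(confusion = list(tp = report$cm$tp, fp = report$cm$fp,
                               tn = report$cm$tn, fn = report$cm$fn),
              acc = report$acc, sn = report$sn, sp = report$sp,
              mcc = report$mcc, mcc_degenerate = report$mcc_degenerate,
              auc = report$auc, threshold = report$threshold)
  if (!is.null(report$fold_acc)) {
    out$fold_acc_mean <- mean(report$fold_acc)
    out$fold_acc_sd <- stats::sd(report$fold_acc)
    out$fold_acc <- report$fold_acc
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc_path)) {
    utils::write.table(report$roc, roc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
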