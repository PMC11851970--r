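#' Confusion counts for binary epoch classification
#'
#' Preictal (label 1) is the positive class: TP counts preictal epochs
#' flagged preictal, TN baseline epochs kept baseline.
#'
#' @param truth,pred integer vectors in `{0, 1}`, or leave both missing and
#'   supply counts directly.
#' @param tp,fp,tn,fn direct non-negative counts (alternative interface).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(truth = NULL, pred = NULL,
                             tp = NULL, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(truth)) {
    stopifnot(length(truth) == length(pred),
              all(truth %in% c(0, 1)), all(pred %in% c(0, 1)))
    tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
    tn <- sum(truth == 0 & pred == 0); fn <- sum(truth == 1 & pred == 0)
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  structure(as.list(counts), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' precision = TP/(TP+FP), F1 = harmonic mean of precision and sensitivity.
#' All reported as percentages. A metric with a zero denominator is reported
#' as `NA` with the reason in the `undefined` element rather than silently
#' as 0.
#'
#' @param counts a [confusion_counts()].
#' @return An object of class `metrics_report` (also a list): `accuracy`,
#'   `sensitivity`, `precision`, `f1` in percent, `counts`, `undefined`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("no evaluated epochs")
  undefined <- list()
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined[[name]] <<- paste0("denominator zero (", name, ")")
      return(NA_real_)
    }
    100 * num / den
  }
  acc <- 100 * (tp + tn) / total
  sens <- ratio(tp, tp + fn, "sensitivity")
  prec <- ratio(tp, tp + fp, "precision")
  f1 <- if (is.na(sens) || is.na(prec)) {
    undefined[["f1"]] <- "precision or sensitivity undefined"
    NA_real_
  } else if (sens + prec == 0) {
    undefined[["f1"]] <- "precision + sensitivity = 0"
    NA_real_
  } else 2 * prec * sens / (prec + sens)
  structure(list(accuracy = acc, sensitivity = sens, precision = prec,
                 f1 = f1, counts = counts, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("accuracy %s | sensitivity %s | precision %s | F1 %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$precision),
              fmt(x$f1)))
  invisible(x)
}

#' ROC curve and AUC from continuous ensemble scores
#'
#' Threshold sweep over the unique score values with trapezoidal area; the
#' AUC equals the scaled Mann-Whitney U statistic. Scores are oriented so
#' that larger values indicate the preictal class.
#'
#' @param scores numeric vector of continuous classifier scores.
#' @param labels true labels in `{0, 1}`.
#' @return list with `auc` (numeric in `[0, 1]`) and `curve` (data frame
#'   with `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2)
    stop("ROC needs both classes present")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- data.frame(threshold = r$thresholds,
                      fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  list(auc = as.numeric(r$auc), curve = curve)
}
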