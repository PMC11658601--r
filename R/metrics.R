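#' Segmentation evaluation metrics
#'
#' Computes precision, recall, F1 and mean intersection-over-union for a
#' binary ground/canopy segmentation, all on the percent scale.
#' Precision, recall and F1 treat `positive_class` (canopy by default)
#' as positive; mIoU averages the per-class IoU over both classes.
#'
#' @param pred,truth integer label vectors of equal length (0/1).
#' @param positive_class label treated as positive (default 1, canopy).
#' @return List of class `seg_metrics` with elements `precision`,
#'   `recall`, `f1`, `miou`, each in \[0, 100\].
#' @export
segmentation_metrics <- function(pred, truth, positive_class = 1L) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stop("pred and truth must be non-empty and of equal length", call. = FALSE)
  pos <- pred == positive_class & truth == positive_class
  tp <- sum(pos)
  fp <- sum(pred == positive_class & truth != positive_class)
  fn <- sum(pred != positive_class & truth == positive_class)
  tn <- length(pred) - tp - fp - fn
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  iou_pos <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  iou_neg <- if (tn + fp + fn == 0) 1 else tn / (tn + fp + fn)
  structure(list(precision = 100 * precision, recall = 100 * recall,
                 f1 = 100 * f1, miou = 100 * (iou_pos + iou_neg) / 2),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("precision %.2f  recall %.2f  F1 %.2f  mIoU %.2f (percent)\n",
              x$precision, x$recall, x$f1, x$miou))
  invisible(x)
}
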