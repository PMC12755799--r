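#' Confusion counts for a pair of binary masks
#'
#' @param pred,gt Binary arrays (values 0/1) of identical shape.
#' @return Named integer-ish vector `c(tp, fp, fn, tn)`; the four counts
#'   always sum to the number of voxels.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim2(pred), dim2(gt)))
    stop_config("confusion_counts: mask shapes differ (%s vs %s)",
                paste(dim2(pred), collapse = "x"), paste(dim2(gt), collapse = "x"))
  p <- as.numeric(pred); g <- as.numeric(gt)
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stop_config("confusion_counts: masks must be strictly binary (0/1)")
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  tn <- sum(p == 0 & g == 0)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# metrics from pooled confusion counts; 0/0 returns `empty` (1 when the
# degenerate case means perfect agreement, 0 otherwise)
ratio_or <- function(num, den, empty) if (den == 0) empty else num / den

#' Segmentation metrics from confusion counts
#'
#' Computes IoU, Dice (DSC), recall and precision from pooled voxel counts.
#' When both masks are empty every metric is 1 (perfect agreement); an
#' empty prediction against a nonempty truth (or vice versa) scores 0.
#'
#' @param counts Vector as returned by [confusion_counts()].
#' @return List with `iou`, `dsc`, `recall`, `precision` and the counts.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  both_empty <- (tp + fp + fn) == 0
  list(
    iou = ratio_or(tp, tp + fp + fn, 1),
    dsc = ratio_or(2 * tp, 2 * tp + fp + fn, 1),
    recall = if (both_empty) 1 else ratio_or(tp, tp + fn, 0),
    precision = if (both_empty) 1 else ratio_or(tp, tp + fp, 0),
    tp = tp, fp = fp, fn = fn, tn = counts[["tn"]]
  )
}

#' @rdname seg_dsc
#' @export
seg_iou <- function(pred, gt) metrics_from_counts(confusion_counts(pred, gt))$iou

#' Dice similarity coefficient (and friends) for binary masks
#'
#' `seg_dsc` computes 2 tp / (2 tp + fp + fn); `seg_iou` computes
#' tp / (tp + fp + fn) (Jaccard); `seg_recall` and `seg_precision` are the
#' usual sensitivity and positive predictive value. The identity
#' dsc = 2 iou / (1 + iou) holds exactly for pooled counts.
#'
#' @inheritParams confusion_counts
#' @return A fraction in \[0, 1\].
#' @export
seg_dsc <- function(pred, gt) metrics_from_counts(confusion_counts(pred, gt))$dsc

#' @rdname seg_dsc
#' @export
seg_recall <- function(pred, gt) metrics_from_counts(confusion_counts(pred, gt))$recall

#' @rdname seg_dsc
#' @export
seg_precision <- function(pred, gt) metrics_from_counts(confusion_counts(pred, gt))$precision

#' Mean absolute error of a forecast, with population spread
#'
#' @param predicted,actual Equal-length numeric sequences.
#' @return `c(mean, std)` of the absolute errors; `std` is the population
#'   (divide-by-n) standard deviation, matching "mean +/- std" table style.
#' @export
mae_stats <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) == 0L)
    stop_config("mae_stats: sequences must have equal nonzero length (%d vs %d)",
                length(predicted), length(actual))
  err <- abs(predicted - actual)
  m <- mean(err)
  c(mean = m, std = sqrt(mean((err - m)^2)))
}
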