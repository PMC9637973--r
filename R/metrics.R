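#' Binary cross-entropy between a probability map and a binary mask
#'
#' Mean over pixels of `-(y log x + (1 - y) log(1 - x))`, with predictions
#' clamped to `[eps, 1 - eps]` so the value is always finite. The per-pixel
#' mean (rather than a sum) makes the magnitude independent of image and
#' batch size.
#'
#' @param pred numeric array of predicted foreground probabilities in \[0, 1\].
#' @param target binary array of the same shape.
#' @param eps clamping constant, default `1e-7`.
#' @return nonnegative scalar.
#' @examples
#' bce_loss(matrix(0.5, 2, 2), matrix(c(0, 1, 0, 1), 2)) # log(2)
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target))) {
    stop("pred and target shapes differ")
  }
  x <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(x) + (1 - target) * log(1 - x))
}

#' Pixel-wise confusion counts between two binary masks
#'
#' @param pred,gt binary arrays of identical shape.
#' @return one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred) %||% length(pred), dim(gt) %||% length(gt))) {
    stop("pred and gt shapes differ")
  }
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1))) {
    stop("confusion_counts expects strictly binary masks")
  }
  tibble::tibble(
    tp = sum(pred == 1 & gt == 1),
    fp = sum(pred == 1 & gt == 0),
    fn = sum(pred == 0 & gt == 1),
    tn = sum(pred == 0 & gt == 0)
  )
}

# shared degenerate-mask convention:
#  both masks empty -> all four metrics are 1 (perfect agreement);
#  exactly one empty -> all four are 0.
overlap_metric <- function(pred, gt, f) {
  a <- sum(pred); b <- sum(gt)
  if (a == 0 && b == 0) return(1)
  if (a == 0 || b == 0) return(0)
  f(sum(pred * gt), a, b)
}

#' Overlap and pixel-classification metrics for binary segmentation
#'
#' `dice` is `2|X intersect Y| / (|X| + |Y|)`; `jaccard` is
#' `|X intersect Y| / |X union Y|`; `precision` is `TP / (TP + FP)` and
#' `recall` is `TP / (TP + FN)`. When both masks are empty all four equal 1;
#' when exactly one is empty all four equal 0.
#'
#' @param pred,gt binary arrays of identical shape.
#' @return scalar in \[0, 1\].
#' @examples
#' p <- c(1, 1, 0, 0); g <- c(1, 0, 1, 0)
#' dice(p, g)     # 0.5
#' jaccard(p, g)  # 1/3
#' @export
dice <- function(pred, gt) {
  overlap_metric(pred, gt, function(i, a, b) 2 * i / (a + b))
}

#' @rdname dice
#' @export
jaccard <- function(pred, gt) {
  overlap_metric(pred, gt, function(i, a, b) i / (a + b - i))
}

#' @rdname dice
#' @export
precision <- function(pred, gt) {
  overlap_metric(pred, gt, function(i, a, b) i / a)
}

#' @rdname dice
#' @export
recall <- function(pred, gt) {
  overlap_metric(pred, gt, function(i, a, b) i / b)
}

#' All four segmentation metrics as a one-row tibble
#'
#' @param pred,gt binary arrays of identical shape.
#' @return tibble with columns `dice`, `jaccard`, `precision`, `recall`.
#' @export
seg_metrics <- function(pred, gt) {
  tibble::tibble(
    dice = dice(pred, gt), jaccard = jaccard(pred, gt),
    precision = precision(pred, gt), recall = recall(pred, gt)
  )
}
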