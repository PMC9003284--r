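# Segmentation evaluation: confusion counts and the metric suite
# (precision, recall, accuracy, weighted F-measure, MCC, Jaccard, Dice,
# specificity), plus the adaptive 2*mean threshold.
#
# Undefined metrics (zero denominators) are reported as NA_real_, never
# silently 0 — with the single documented exception of MCC, which returns 0
# when a confusion-matrix marginal is empty (the no-information value).

#' Confusion counts of two binary masks
#'
#' Masks may be logical or 0/1 numeric; `TRUE`/1 is the positive class as
#' given. Polarity is the caller's choice: pass negated masks to score the
#' complementary class.
#'
#' @param pred predicted binary mask.
#' @param gt ground-truth binary mask, same shape.
#' @return object of class `confusion`: list with integer `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)) || length(pred) != length(gt))
    stop("mask shapes differ", call. = FALSE)
  p <- as.logical(pred); g <- as.logical(gt)
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 TN = sum(!p & !g), FN = sum(!p & g)),
            class = "confusion")
}

#' Precision and recall
#'
#' @param c a [confusion()] object.
#' @return named numeric vector `c(precision =, recall =)`; a component is
#'   `NA` when its denominator (predicted / ground-truth positives) is
#'   empty.
#' @export
precision_recall <- function(c) {
  prec <- if (c$TP + c$FP > 0) c$TP / (c$TP + c$FP) else NA_real_
  rec <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_
  c(precision = prec, recall = rec)
}

#' Pixel accuracy
#' @param c a [confusion()] object.
#' @return `(TP + TN) / N`, or `NA` on an empty comparison.
#' @export
accuracy <- function(c) {
  n <- c$TP + c$FP + c$TN + c$FN
  if (n == 0) return(NA_real_)
  (c$TP + c$TN) / n
}

#' Adaptive segmentation threshold: twice the map mean
#'
#' @param map numeric matrix (sharpness or edge map).
#' @return `2 * mean(map)`.
#' @export
adaptive_threshold <- function(map) 2 * mean(map)

#' Weighted F-measure
#'
#' `F = (1 + k2) P R / (k2 P + R)` with the precision-favoring weight
#' `k2 = 0.3` by default.
#'
#' @param precision,recall scalars in [0,1].
#' @param kappa_sq the squared weight.
#' @return F-measure, or `NA` when P = R = 0 or either input is `NA`.
#' @export
f_measure <- function(precision, recall, kappa_sq = 0.3) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision == 0 && recall == 0) return(NA_real_)
  (1 + kappa_sq) * precision * recall / (kappa_sq * precision + recall)
}

#' Matthews correlation coefficient
#'
#' Standard MCC with the square-root denominator, ranged in [-1, 1];
#' returns 0 when any marginal of the confusion matrix is zero (documented
#' convention for the degenerate one-class case).
#'
#' @param c a [confusion()] object.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(c) {
  # doubles: the marginal product overflows 32-bit integers on large masks
  tp <- as.numeric(c$TP); fp <- as.numeric(c$FP)
  tn <- as.numeric(c$TN); fn <- as.numeric(c$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Weighted Jaccard coefficient
#'
#' `sum(min(u, v)) / sum(max(u, v))` over non-negative vectors or masks;
#' reduces to intersection-over-union on binary masks. Two empty inputs
#' compare as identical: J = 1.
#'
#' @param u,v non-negative numeric or logical arrays of equal length.
#' @return Jaccard coefficient in [0, 1].
#' @export
jaccard <- function(u, v) {
  if (length(u) != length(v)) stop("lengths differ", call. = FALSE)
  u <- as.numeric(u); v <- as.numeric(v)
  if (any(u < 0) || any(v < 0)) stop("inputs must be non-negative", call. = FALSE)
  den <- sum(pmax(u, v))
  if (den == 0) return(1)
  sum(pmin(u, v)) / den
}

#' Dice similarity coefficient
#' @param c a [confusion()] object.
#' @return `2 TP / (2 TP + FP + FN)`, or `NA` when both masks are empty.
#' @export
dice <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) return(NA_real_)
  2 * c$TP / den
}

#' Specificity (true-negative rate)
#' @param c a [confusion()] object.
#' @return `TN / (TN + FP)`, or `NA` when there are no real negatives.
#' @export
specificity <- function(c) {
  if (c$TN + c$FP == 0) return(NA_real_)
  c$TN / (c$TN + c$FP)
}

#' Full metric report for a predicted mask against ground truth
#'
#' @param pred,gt binary masks, same shape; `TRUE`/1 is the positive class.
#' @param kappa_sq weight for [f_measure()].
#' @return named list of all metrics plus the confusion counts.
#' @export
metrics_report <- function(pred, gt, kappa_sq = 0.3) {
  cc <- confusion(pred, gt)
  pr <- precision_recall(cc)
  list(precision = unname(pr["precision"]), recall = unname(pr["recall"]),
       accuracy = accuracy(cc),
       f_kappa = f_measure(pr["precision"], pr["recall"], kappa_sq),
       mcc = mcc(cc), jaccard = jaccard(pred, gt), dice = dice(cc),
       specificity = specificity(cc), kappa_sq = kappa_sq,
       confusion = cc)
}
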