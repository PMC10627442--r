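PROB_EPS <- 1e-7

clipProb <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

checkSameShape <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- length(a)
  if (is.null(db)) db <- length(b)
  if (!identical(da, db))
    stop("shape mismatch between prediction and target")
}

#' Alpha-balanced focal loss
#'
#' Mean over pixels of \code{-alpha_t * (1 - P_t)^gamma * log(P_t)} with
#' natural logarithm, where \code{P_t} is the predicted probability of the
#' true class (\code{p} for foreground pixels, \code{1 - p} for background)
#' and \code{alpha_t} is \code{alpha} for foreground and \code{1 - alpha} for
#' background. Probabilities are clipped to \code{[1e-7, 1 - 1e-7]}.
#'
#' With \code{gamma = 0} and \code{alpha = 0.5} this is half the mean binary
#' cross-entropy.
#'
#' @param prob Predicted probabilities in [0, 1] (any shape).
#' @param target Binary mask of the same shape.
#' @param cfg A \code{\link{lossConfig}}.
#' @return Non-negative scalar loss.
#' @export
focalLoss <- function(prob, target, cfg = lossConfig()) {
  checkSameShape(prob, target)
  p <- clipProb(prob)
  pt <- ifelse(target == 1, p, 1 - p)
  at <- ifelse(target == 1, cfg@alpha, 1 - cfg@alpha)
  mean(-at * (1 - pt)^cfg@gamma * log(pt))
}

# d(focal)/d(prob), same reduction (mean over the n supplied pixels).
focalLossGrad <- function(prob, target, cfg = lossConfig()) {
  p <- clipProb(prob)
  t1 <- target == 1
  pt <- ifelse(t1, p, 1 - p)
  at <- ifelse(t1, cfg@alpha, 1 - cfg@alpha)
  g <- cfg@gamma
  # dL/dpt of the per-pixel term, then chain through dpt/dp = +/-1
  dpt <- -at * (-g * (1 - pt)^(pmax(g - 1, 0)) * log(pt) * (g > 0) +
                  (1 - pt)^g / pt)
  dpt * ifelse(t1, 1, -1) / length(p)
}

#' Dice similarity coefficient (soft)
#'
#' \code{(2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) +
#' smooth)}. For strictly binary inputs and \code{smooth -> 0} this equals
#' the count form \code{2 TP / (2 TP + FP + FN)}.
#'
#' @param pred Probability map or binary mask.
#' @param target Binary mask, same shape.
#' @param smooth Smoothing constant (default 1).
#' @return Scalar in [0, 1].
#' @export
diceCoefficient <- function(pred, target, smooth = 1) {
  checkSameShape(pred, target)
  (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)
}

#' Dice loss
#'
#' \code{1 - diceCoefficient(pred, target, smooth)}.
#'
#' @inheritParams diceCoefficient
#' @return Scalar in [0, 1].
#' @export
diceLoss <- function(pred, target, smooth = 1) {
  1 - diceCoefficient(pred, target, smooth)
}

# d(diceLoss)/d(pred)
diceLossGrad <- function(pred, target, smooth = 1) {
  I <- sum(pred * target)
  U <- sum(pred) + sum(target)
  -(2 * target * (U + smooth) - (2 * I + smooth)) / (U + smooth)^2
}

#' Hybrid focal + dice loss
#'
#' The exact sum \code{focalLoss + diceLoss} (dice uses the soft form with
#' \code{cfg@smooth}).
#'
#' @inheritParams focalLoss
#' @return Non-negative scalar loss.
#' @export
hybridLoss <- function(prob, target, cfg = lossConfig()) {
  focalLoss(prob, target, cfg) + diceLoss(prob, target, cfg@smooth)
}

hybridLossGrad <- function(prob, target, cfg = lossConfig()) {
  focalLossGrad(prob, target, cfg) + diceLossGrad(prob, target, cfg@smooth)
}

#' Pixel-wise confusion counts
#'
#' Tallies true/false positives/negatives between two binary masks.
#' Foreground (tumor) is the positive class.
#'
#' @param pred,target Binary masks (values in \{0, 1\}) of the same shape.
#' @return List with integers \code{tp}, \code{tn}, \code{fp}, \code{fn}.
#' @export
confusionCounts <- function(pred, target) {
  checkSameShape(pred, target)
  if (!all(pred %in% c(0, 1)) || !all(target %in% c(0, 1)))
    stop("confusionCounts requires strictly binary inputs")
  tp <- sum(pred == 1 & target == 1)
  tn <- sum(pred == 0 & target == 0)
  fp <- sum(pred == 1 & target == 0)
  fn <- sum(pred == 0 & target == 1)
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Intersection over union (Jaccard index)
#'
#' \code{tp / (tp + fp + fn)}; the empty-vs-empty case (no foreground in
#' either mask) is defined as 1.
#'
#' @param counts Confusion counts from \code{\link{confusionCounts}}.
#' @return Scalar in [0, 1].
#' @export
iouScore <- function(counts) {
  denom <- counts$tp + counts$fp + counts$fn
  if (denom == 0) return(1)
  counts$tp / denom
}

#' Pixel accuracy
#'
#' \code{(tp + tn) / (tp + tn + fp + fn)}.
#'
#' @param counts Confusion counts from \code{\link{confusionCounts}}.
#' @return Scalar in [0, 1].
#' @export
pixelAccuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("empty confusion table")
  (counts$tp + counts$tn) / total
}

# Hard dice from counts; empty-vs-empty convention = 1.
diceFromCounts <- function(counts) {
  denom <- 2 * counts$tp + counts$fp + counts$fn
  if (denom == 0) return(1)
  2 * counts$tp / denom
}

#' Per-image segmentation metrics
#'
#' Thresholds the probability map at 0.5 (strict), compares with the target
#' mask and returns pixel accuracy, IoU and DSC. The empty-vs-empty
#' convention is IoU = DSC = 1.
#'
#' @param prob Probability map.
#' @param target Binary mask, same shape.
#' @param threshold Binarization threshold (default 0.5).
#' @return Named numeric vector \code{c(acc_p, iou, dsc)}, values in [0, 1].
#' @export
segmentationMetrics <- function(prob, target, threshold = 0.5) {
  counts <- confusionCounts(predictMask(prob, threshold), target)
  c(acc_p = pixelAccuracy(counts), iou = iouScore(counts),
    dsc = diceFromCounts(counts))
}

#' Threshold a probability map into a binary mask
#'
#' \code{pixel = 1} iff \code{prob > threshold} (strict).
#'
#' @param prob Probability map with values in [0, 1].
#' @param threshold Scalar in [0, 1].
#' @return Binary array of the same shape.
#' @export
predictMask <- function(prob, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  (prob > threshold) * 1
}
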