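#' @import methods
NULL

#' Network architecture configuration
#'
#' Describes a DBU-Net or GSU-Net computation graph: encoder depth, channel
#' width at the first level (doubling per level), dropout probability applied
#' after each max-pooling step, spatial input size, and whether the dual
#' (edge-fused) encoder is built.
#'
#' @slot levels Encoder depth (number of pool steps).
#' @slot baseChannels Channels at the first encoder level; doubles per level.
#' @slot dropoutRate Dropout probability applied after each pooling step.
#' @slot inputSize Integer length-2 (H, W); must be divisible by 2^levels.
#' @slot fusion "dual" for DBU-Net, "none" for the single-branch GSU-Net.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    levels = "integer",
    baseChannels = "integer",
    dropoutRate = "numeric",
    inputSize = "integer",
    fusion = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (object@levels < 1L) msg <- c(msg, "levels must be >= 1")
    if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      msg <- c(msg, "dropoutRate must be in [0, 1)")
    if (length(object@inputSize) != 2L || any(object@inputSize < 1L))
      msg <- c(msg, "inputSize must be two positive integers")
    if (any(object@inputSize %% 2L^object@levels != 0L))
      msg <- c(msg, "inputSize must be divisible by 2^levels")
    if (!object@fusion %in% c("dual", "none"))
      msg <- c(msg, "fusion must be 'dual' or 'none'")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn ModelConfig-class Constructor. Defaults follow the full-scale
#'   architecture (depth 4, 64 base channels, 256x256 input); tests use the
#'   tiny preset (depth 2, base 8, 64x64).
#' @param levels,baseChannels,dropoutRate,inputSize,fusion See slots.
#' @return A \code{ModelConfig} object.
#' @export
modelConfig <- function(levels = 4L, baseChannels = 64L, dropoutRate = 0.2,
                        inputSize = c(256L, 256L), fusion = c("dual", "none")) {
  fusion <- match.arg(fusion)
  new("ModelConfig",
    levels = as.integer(levels), baseChannels = as.integer(baseChannels),
    dropoutRate = as.numeric(dropoutRate), inputSize = as.integer(inputSize),
    fusion = fusion)
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: %s encoder, depth %d, base %d channels, input %dx%d, dropout %.2f\n",
    if (object@fusion == "dual") "dual-branch" else "single-branch",
    object@levels, object@baseChannels,
    object@inputSize[1], object@inputSize[2], object@dropoutRate))
})

#' Training configuration
#'
#' Optimizer and schedule settings for fold training: Adam with initial
#' learning rate \code{initialLr}, reduce-on-plateau decay (multiply by
#' \code{decayFactor} after \code{plateauPatience} epochs without a
#' validation-loss improvement of at least \code{minDelta}), and early
#' stopping with best-weight restoration after \code{earlyStopPatience}
#' non-improving epochs.
#'
#' @slot batchSize Mini-batch size.
#' @slot maxEpochs Maximum number of epochs.
#' @slot initialLr Initial Adam learning rate.
#' @slot plateauPatience Epochs without improvement before a learning-rate cut.
#' @slot decayFactor Multiplicative learning-rate decay factor in (0, 1).
#' @slot minDelta Minimum validation-loss decrease that counts as improvement.
#' @slot earlyStopPatience Non-improving epochs before training stops.
#' @slot valFraction Fraction of the training fold held out for monitoring.
#' @slot loss "hybrid" (focal + dice) or "dice".
#' @slot seed Integer seed controlling weight init, batch order and dropout.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    batchSize = "integer", maxEpochs = "integer", initialLr = "numeric",
    plateauPatience = "integer", decayFactor = "numeric", minDelta = "numeric",
    earlyStopPatience = "integer", valFraction = "numeric",
    loss = "character", seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
    if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be positive")
    if (object@initialLr <= 0) msg <- c(msg, "initialLr must be positive")
    if (object@decayFactor <= 0 || object@decayFactor >= 1)
      msg <- c(msg, "decayFactor must be in (0, 1)")
    if (object@valFraction < 0 || object@valFraction >= 1)
      msg <- c(msg, "valFraction must be in [0, 1)")
    if (!object@loss %in% c("hybrid", "dice"))
      msg <- c(msg, "loss must be 'hybrid' or 'dice'")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn TrainConfig-class Constructor. Defaults are the tuned
#'   full-scale settings (batch 16, 50 epochs, Adam at 1e-4, plateau patience
#'   3, decay 0.2).
#' @param batchSize,maxEpochs,initialLr,plateauPatience,decayFactor,minDelta
#'   See slots.
#' @param earlyStopPatience,valFraction,loss,seed See slots.
#' @return A \code{TrainConfig} object.
#' @export
trainConfig <- function(batchSize = 16L, maxEpochs = 50L, initialLr = 1e-4,
                        plateauPatience = 3L, decayFactor = 0.2,
                        minDelta = 1e-4, earlyStopPatience = 8L,
                        valFraction = 0.1, loss = c("hybrid", "dice"),
                        seed = 42L) {
  loss <- match.arg(loss)
  new("TrainConfig",
    batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
    initialLr = as.numeric(initialLr),
    plateauPatience = as.integer(plateauPatience),
    decayFactor = as.numeric(decayFactor), minDelta = as.numeric(minDelta),
    earlyStopPatience = as.integer(earlyStopPatience),
    valFraction = as.numeric(valFraction), loss = loss, seed = as.integer(seed))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(paste0("TrainConfig: batch %d, <=%d epochs, Adam lr %.2g, ",
      "plateau(patience %d, factor %.2g), early stop %d, loss '%s', seed %d\n"),
    object@batchSize, object@maxEpochs, object@initialLr,
    object@plateauPatience, object@decayFactor, object@earlyStopPatience,
    object@loss, object@seed))
})

#' Loss configuration
#'
#' Parameters of the hybrid focal + dice loss: focusing parameter
#' \code{gamma}, positive-class weight \code{alpha} (negatives get
#' \code{1 - alpha}), and the dice smoothing constant.
#'
#' @slot gamma Focal focusing parameter, in [0, 5].
#' @slot alpha Positive-class weighting factor, in (0, 1).
#' @slot smooth Dice smoothing constant, > 0.
#' @exportClass LossConfig
setClass("LossConfig",
  representation(gamma = "numeric", alpha = "numeric", smooth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@gamma < 0 || object@gamma > 5)
      msg <- c(msg, "gamma must be in [0, 5]")
    if (object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "alpha must be in (0, 1)")
    if (object@smooth <= 0) msg <- c(msg, "smooth must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn LossConfig-class Constructor (defaults gamma 2, alpha 0.25,
#'   smooth 1).
#' @param gamma,alpha,smooth See slots.
#' @return A \code{LossConfig} object.
#' @export
lossConfig <- function(gamma = 2, alpha = 0.25, smooth = 1) {
  new("LossConfig", gamma = as.numeric(gamma), alpha = as.numeric(alpha),
      smooth = as.numeric(smooth))
}

setMethod("show", "LossConfig", function(object) {
  cat(sprintf("LossConfig: gamma %.3g, alpha %.3g, dice smooth %.3g\n",
    object@gamma, object@alpha, object@smooth))
})

#' Synthetic phantom configuration
#'
#' Controls the speckle-phantom generator: image size, lesion ellipse
#' semi-axis range, lesion darkening, speckle dispersion, boundary blur and
#' radial jitter, and the probability that the ground-truth mask is emitted
#' as two overlapping components (exercising mask merging).
#'
#' @slot size Integer (H, W).
#' @slot lesionAxesRange Pixel range for the ellipse semi-axes.
#' @slot intensityDrop Lesion darkening factor in (0, 1).
#' @slot speckleScale Multiplicative speckle dispersion (0 disables).
#' @slot blurSigma Gaussian blur (pixels) applied to the lesion boundary.
#' @slot boundaryJitter Radial perturbation amplitude (fraction of radius).
#' @slot multiMaskProb Probability of splitting the mask into two parts.
#' @slot seed Integer seed; generation is deterministic in (seed, index).
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(
    size = "integer", lesionAxesRange = "numeric", intensityDrop = "numeric",
    speckleScale = "numeric", blurSigma = "numeric", boundaryJitter = "numeric",
    multiMaskProb = "numeric", seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@size) != 2L || any(object@size < 16L))
      msg <- c(msg, "size must be two integers >= 16")
    if (length(object@lesionAxesRange) != 2L ||
        any(object@lesionAxesRange <= 0))
      msg <- c(msg, "lesionAxesRange must be two positive values")
    if (max(object@lesionAxesRange) * 2.2 > min(object@size))
      msg <- c(msg, "lesion cannot fit inside the image with margin")
    if (object@intensityDrop < 0 || object@intensityDrop >= 1)
      msg <- c(msg, "intensityDrop must be in [0, 1)")
    if (object@multiMaskProb < 0 || object@multiMaskProb > 1)
      msg <- c(msg, "multiMaskProb must be in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn PhantomConfig-class Constructor. Defaults emulate BUSI-like
#'   appearance at 128x128: hypoechoic (darker) elliptical lesion with fuzzy,
#'   jittered boundary embedded in smoothed multiplicative speckle.
#' @param size,lesionAxesRange,intensityDrop,speckleScale,blurSigma See slots.
#' @param boundaryJitter,multiMaskProb,seed See slots.
#' @return A \code{PhantomConfig} object.
#' @export
phantomConfig <- function(size = c(128L, 128L), lesionAxesRange = c(12, 28),
                          intensityDrop = 0.5, speckleScale = 0.35,
                          blurSigma = 1.5, boundaryJitter = 0.12,
                          multiMaskProb = 0.05, seed = 42L) {
  new("PhantomConfig",
    size = as.integer(size), lesionAxesRange = as.numeric(lesionAxesRange),
    intensityDrop = as.numeric(intensityDrop),
    speckleScale = as.numeric(speckleScale), blurSigma = as.numeric(blurSigma),
    boundaryJitter = as.numeric(boundaryJitter),
    multiMaskProb = as.numeric(multiMaskProb), seed = as.integer(seed))
}

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(paste0("PhantomConfig: %dx%d, axes [%.3g, %.3g], drop %.2f, ",
      "speckle %.2f, blur %.2g px, jitter %.2f, multi-mask p %.2f, seed %d\n"),
    object@size[1], object@size[2], object@lesionAxesRange[1],
    object@lesionAxesRange[2], object@intensityDrop, object@speckleScale,
    object@blurSigma, object@boundaryJitter, object@multiMaskProb,
    object@seed))
})

#' A built segmentation network
#'
#' Holds the architecture configuration and the named list of trainable
#' parameters (convolution kernels, biases, and for the dual-branch model the
#' per-level fusion scalars). Use \code{\link{buildDBUNet}} /
#' \code{\link{buildGSUNet}} to construct, \code{\link{predictProb}} for the
#' forward pass, and \code{\link{nParameters}} / \code{\link{fusionWeights}}
#' as accessors.
#'
#' @slot config A \code{ModelConfig}.
#' @slot params Named list of numeric arrays (trainable parameters).
#' @exportClass UNetModel
setClass("UNetModel",
  representation(config = "ModelConfig", params = "list"))

setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  cat(sprintf("%s (depth %d, base %d, input %dx%d)\n",
    if (cfg@fusion == "dual") "DBU-Net" else "GSU-Net",
    cfg@levels, cfg@baseChannels, cfg@inputSize[1], cfg@inputSize[2]))
  np <- vapply(object@params, length, integer(1))
  cat(sprintf("  %d parameter tensors, %d trainable parameters\n",
    length(np), sum(np)))
  if (cfg@fusion == "dual") {
    fw <- fusionWeights(object)
    cat("  fusion weights:",
        paste(sprintf("L%d(wx=%.3g, wy=%.3g)", seq_len(cfg@levels),
                      fw$wx, fw$wy), collapse = ", "), "\n")
  }
})

#' Number of trainable parameters
#' @param model A \code{UNetModel}.
#' @return Integer count of scalar trainable parameters.
#' @export
nParameters <- function(model) {
  stopifnot(is(model, "UNetModel"))
  sum(vapply(model@params, length, integer(1)))
}

#' Per-level fusion weights of a dual-branch model
#' @param model A \code{UNetModel} built with \code{fusion = "dual"}.
#' @return List with numeric vectors \code{wx} and \code{wy} (one per level).
#' @export
fusionWeights <- function(model) {
  stopifnot(is(model, "UNetModel"))
  if (model@config@fusion != "dual")
    stop("model has no fusion weights (single-branch)")
  L <- model@config@levels
  list(
    wx = vapply(seq_len(L), function(l)
      model@params[[sprintf("fuse_l%d_wx", l)]], numeric(1)),
    wy = vapply(seq_len(L), function(l)
      model@params[[sprintf("fuse_l%d_wy", l)]], numeric(1))
  )
}
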