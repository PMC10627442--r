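#' Reduce-on-plateau learning-rate schedule
#'
#' Pure function of a validation-loss trace. The learning rate starts at
#' \code{lr0}; an epoch improves when its loss is below the running best by
#' more than \code{minDelta}. After \code{patience} consecutive non-improving
#' epochs the rate is multiplied by \code{factor} (taking effect from the
#' next epoch) and the patience counter resets.
#'
#' @param valLosses Numeric vector, one validation loss per epoch.
#' @param lr0 Initial learning rate.
#' @param patience Non-improving epochs tolerated before a cut.
#' @param factor Multiplicative decay factor in (0, 1).
#' @param minDelta Minimum decrease that counts as improvement.
#' @return Numeric vector: the learning rate in effect during each epoch.
#' @examples
#' # one improving epoch then seven flat ones: 1e-4 -> 2e-5 -> 4e-6
#' unique(plateauSchedule(rep(1, 8), 1e-4, 3, 0.2))
#' @export
plateauSchedule <- function(valLosses, lr0 = 1e-4, patience = 3L,
                            factor = 0.2, minDelta = 1e-4) {
  lr <- lr0
  best <- Inf
  wait <- 0L
  out <- numeric(length(valLosses))
  for (e in seq_along(valLosses)) {
    out[e] <- lr
    if (valLosses[e] < best - minDelta) {
      best <- valLosses[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- lr * factor
        wait <- 0L
      }
    }
  }
  out
}

batchLoss <- function(model, gray, mask, edge, lossCfg, loss) {
  fw <- modelForward(model, gray, edge, train = FALSE)
  B <- dim(gray)[4]
  lv <- 0
  for (i in seq_len(B)) {
    pi <- fw$prob[, , 1, i]; ti <- mask[, , 1, i]
    lv <- lv + if (loss == "hybrid") hybridLoss(pi, ti, lossCfg)
      else diceLoss(pi, ti, lossCfg@smooth)
  }
  lv / B
}

subsetBatch <- function(x, idx) x[, , , idx, drop = FALSE]

#' Fixed-step Adam fit
#'
#' Minimal training loop: shuffled mini-batches, a fixed number of optimizer
#' steps at a constant learning rate. Used for desk-scale overfit and
#' recovery experiments; \code{\link{trainFold}} adds the full monitored
#' protocol.
#'
#' @param model A \code{UNetModel}.
#' @param gray,mask Arrays (H, W, 1, N).
#' @param edge Edge arrays for dual models, else NULL.
#' @param steps Number of optimizer steps.
#' @param batchSize Mini-batch size.
#' @param lr Adam learning rate.
#' @param seed Seed for batch order and dropout.
#' @param lossCfg A \code{\link{lossConfig}}.
#' @param loss "hybrid" or "dice".
#' @param stopFn Optional predicate called with the current model every
#'   \code{checkEvery} steps; training stops early when it returns TRUE.
#' @param checkEvery Interval (steps) for \code{stopFn} checks.
#' @return List with the trained \code{model}, numeric \code{lossHistory}
#'   (length = steps actually run) and \code{stepsRun}.
#' @export
fitSteps <- function(model, gray, mask, edge = NULL, steps = 300L,
                     batchSize = 8L, lr = 1e-3, seed = 42L,
                     lossCfg = lossConfig(), loss = c("hybrid", "dice"),
                     stopFn = NULL, checkEvery = 0L) {
  loss <- match.arg(loss)
  # force inputs before seeding so lazily-evaluated constructors (which may
  # set their own seed) cannot disturb the batch/dropout RNG stream
  force(model); force(gray); force(mask); force(edge)
  set.seed(as.integer(seed))
  n <- dim(gray)[4]
  state <- adamInit(model@params)
  hist <- numeric(steps)
  order <- sample.int(n)
  pos <- 1L
  for (s in seq_len(steps)) {
    if (pos + batchSize - 1L > n) {
      order <- sample.int(n)
      pos <- 1L
    }
    idx <- order[pos:min(pos + batchSize - 1L, n)]
    pos <- pos + batchSize
    g <- modelGradients(model,
      subsetBatch(gray, idx), subsetBatch(mask, idx),
      if (is.null(edge)) NULL else subsetBatch(edge, idx),
      lossCfg, loss, train = TRUE)
    hist[s] <- g$loss
    upd <- adamStep(model@params, g$grads, state, lr)
    model@params <- upd$params
    state <- upd$state
    if (!is.null(stopFn) && checkEvery > 0L && s %% checkEvery == 0L &&
        isTRUE(stopFn(model))) {
      hist <- hist[seq_len(s)]
      break
    }
  }
  list(model = model, lossHistory = hist, stepsRun = length(hist))
}

#' Evaluate a model on a set of images
#'
#' Per-image metrics (threshold 0.5), averaged over the set.
#'
#' @param model A \code{UNetModel}.
#' @param gray,mask Arrays (H, W, 1, N).
#' @param edge Edge arrays for dual models, else NULL.
#' @param chunk Images per forward pass (memory control).
#' @return Named numeric vector \code{c(acc_p, iou, dsc)} in [0, 1].
#' @export
evaluateModel <- function(model, gray, mask, edge = NULL, chunk = 8L) {
  n <- dim(gray)[4]
  acc <- matrix(0, n, 3)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    prob <- modelForward(model, subsetBatch(gray, idx),
      if (is.null(edge)) NULL else subsetBatch(edge, idx),
      train = FALSE)$prob
    for (j in seq_along(idx))
      acc[idx[j], ] <- segmentationMetrics(prob[, , 1, j],
                                           mask[, , 1, idx[j]])
  }
  c(acc_p = mean(acc[, 1]), iou = mean(acc[, 2]), dsc = mean(acc[, 3]))
}

#' Train one cross-validation fold with the full monitored protocol
#'
#' Holds out \code{valFraction} of the training fold for monitoring, trains
#' with Adam and the configured loss, applies the reduce-on-plateau schedule
#' and early stopping (best validation weights restored), then evaluates on
#' the fold's test set.
#'
#' @param dataset List as returned by \code{\link{loadDataset}} (or the
#'   phantom generator): \code{gray}, \code{edge}, \code{mask}, \code{id},
#'   \code{class}.
#' @param folds Fold assignment from \code{\link{makeFolds}}.
#' @param foldIndex Which fold serves as the test set.
#' @param modelCfg A \code{\link{modelConfig}}.
#' @param trainCfg A \code{\link{trainConfig}}.
#' @return List with \code{model}, \code{metrics} (one-row data.frame with
#'   fold, acc_p, iou, dsc in percent) and the per-epoch \code{history}.
#' @export
trainFold <- function(dataset, folds, foldIndex, modelCfg = modelConfig(),
                      trainCfg = trainConfig()) {
  sp <- foldSplit(folds, foldIndex)
  tri <- match(sp$train, dataset$id)
  tei <- match(sp$test, dataset$id)
  if (length(tri) == 0 || length(tei) == 0)
    stop("empty train or test set for fold ", foldIndex)
  dual <- modelCfg@fusion == "dual"
  seed <- trainCfg@seed + foldIndex
  set.seed(seed)
  nv <- max(if (trainCfg@valFraction > 0) 1L else 0L,
            floor(trainCfg@valFraction * length(tri)))
  vi <- if (nv > 0) sample(tri, nv) else integer(0)
  ti <- setdiff(tri, vi)

  model <- if (dual) buildDBUNet(modelCfg, seed) else
    buildGSUNet(modelCfg, seed)
  g <- subsetBatch(dataset$gray, ti)
  m <- subsetBatch(dataset$mask, ti)
  e <- if (dual) subsetBatch(dataset$edge, ti) else NULL
  gv <- if (nv > 0) subsetBatch(dataset$gray, vi)
  mv <- if (nv > 0) subsetBatch(dataset$mask, vi)
  ev <- if (dual && nv > 0) subsetBatch(dataset$edge, vi) else NULL

  lossCfg <- lossConfig()
  state <- adamInit(model@params)
  n <- length(ti)
  lr <- trainCfg@initialLr
  best <- Inf
  bestParams <- model@params
  wait <- 0L
  plateauWait <- 0L
  history <- data.frame(epoch = integer(), lr = numeric(),
                        trainLoss = numeric(), valLoss = numeric())
  for (epoch in seq_len(trainCfg@maxEpochs)) {
    order <- sample.int(n)
    epochLoss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = trainCfg@batchSize)) {
      idx <- order[start:min(start + trainCfg@batchSize - 1L, n)]
      gr <- modelGradients(model, subsetBatch(g, idx), subsetBatch(m, idx),
        if (dual) subsetBatch(e, idx) else NULL,
        lossCfg, trainCfg@loss, train = TRUE)
      upd <- adamStep(model@params, gr$grads, state, lr)
      model@params <- upd$params
      state <- upd$state
      epochLoss <- epochLoss + gr$loss
      nb <- nb + 1L
    }
    valLoss <- if (nv > 0) batchLoss(model, gv, mv, ev, lossCfg,
                                     trainCfg@loss) else epochLoss / nb
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
      trainLoss = epochLoss / nb, valLoss = valLoss))
    if (valLoss < best - trainCfg@minDelta) {
      best <- valLoss
      bestParams <- model@params
      wait <- 0L
      plateauWait <- 0L
    } else {
      wait <- wait + 1L
      plateauWait <- plateauWait + 1L
      if (plateauWait >= trainCfg@plateauPatience) {
        lr <- lr * trainCfg@decayFactor
        plateauWait <- 0L
      }
      if (wait >= trainCfg@earlyStopPatience) break
    }
  }
  model@params <- bestParams
  met <- evaluateModel(model, subsetBatch(dataset$gray, tei),
    subsetBatch(dataset$mask, tei),
    if (dual) subsetBatch(dataset$edge, tei) else NULL)
  list(model = model,
       metrics = data.frame(fold = foldIndex,
         acc_p = unname(100 * met["acc_p"]), iou = unname(100 * met["iou"]),
         dsc = unname(100 * met["dsc"]), row.names = NULL),
       history = history)
}

#' Run k-fold cross-validation
#'
#' Builds stratified folds, trains one model per fold with
#' \code{\link{trainFold}}, and collects the per-fold test metrics (percent),
#' one row per fold in fold order.
#'
#' @inheritParams trainFold
#' @param k Number of folds (default 5).
#' @return List with \code{metrics} (data.frame, k rows), \code{folds} and
#'   the list of trained \code{models}.
#' @export
runCrossValidation <- function(dataset, modelCfg = modelConfig(),
                               trainCfg = trainConfig(), k = 5L) {
  folds <- makeFolds(dataset$id, dataset$class, k = k, seed = trainCfg@seed)
  res <- lapply(seq_len(k), function(f)
    trainFold(dataset, folds, f, modelCfg, trainCfg))
  list(metrics = do.call(rbind, lapply(res, `[[`, "metrics")),
       folds = folds,
       models = lapply(res, `[[`, "model"))
}

#' Save / load a trained model
#'
#' Serializes the \code{UNetModel} (configuration plus parameter arrays) with
#' R's native serialization; the round trip reproduces forward outputs
#' bit-for-bit.
#'
#' @param model A \code{UNetModel}.
#' @param path Checkpoint file path.
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "UNetModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  model <- readRDS(path)
  if (!is(model, "UNetModel")) stop("checkpoint does not hold a UNetModel")
  model
}

#' Predict masks for a directory of images
#'
#' Loads every PNG in \code{inDir}, preprocesses it to the model's input size
#' (bilinear resize, 0-1 normalization, Roberts edge map for dual models),
#' and writes one strictly binary 0/255 PNG mask per input image to
#' \code{outDir}, preserving file stems.
#'
#' @param model A \code{UNetModel}.
#' @param inDir Directory of input PNGs.
#' @param outDir Output directory (created if missing).
#' @param threshold Binarization threshold.
#' @return Character vector of written mask paths, invisibly.
#' @export
predictDir <- function(model, inDir, outDir, threshold = 0.5) {
  files <- list.files(inDir, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0) stop("no PNG images in ", inDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  size <- model@config@inputSize
  dual <- model@config@fusion == "dual"
  out <- character(length(files))
  for (i in seq_along(files)) {
    raw <- loadGrayscale(files[i])
    g <- normalizeImage(resizeBilinear(raw, size[1], size[2]))
    e <- if (dual) edgeImage(g, "roberts") else NULL
    prob <- predictProb(model, g, e)
    mask <- predictMask(prob[, , 1, 1], threshold)
    out[i] <- file.path(outDir,
      paste0(sub("\\.png$", "", basename(files[i])), ".png"))
    png::writePNG(mask, out[i])
  }
  invisible(out)
}
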