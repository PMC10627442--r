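# DBU-Net / GSU-Net computation graphs.
#
# Encoder level l (l = 1..L): two 3x3 conv + ReLU (channels base * 2^(l-1)),
# 2x2 max-pool (stride 2), dropout. In the dual model both branches run the
# same block structure on their own input (raw image / binary edge map) and
# then exchange information through the learnable weighted cross-fusion
#   fx' = fx + (wx * fx + wy * fy),   fy' = fy + (wx * fx + wy * fy),
# computed from the pre-update maps, one (wx, wy) pair per level, both
# initialized at exactly 1. Skip connections carry the primary branch's
# conv-block outputs (pre-pool, full resolution); the fused maps feed the
# next level and the bottleneck. Decoder level: bilinear x2 upsampling, 2x2
# conv halving the channels, concatenation with the skip, two 3x3 conv +
# ReLU. A final 1x1 conv + sigmoid yields the probability map.

glorotConv <- function(k, ci, co) {
  lim <- sqrt(6 / (k * k * ci + k * k * co))
  array(stats::runif(k * k * ci * co, -lim, lim), c(k, k, ci, co))
}

buildParams <- function(cfg, seed) {
  set.seed(as.integer(seed))
  L <- cfg@levels
  base <- cfg@baseChannels
  ch <- base * 2L^(seq_len(L) - 1L)
  p <- list()
  branches <- if (cfg@fusion == "dual") c("x", "y") else "x"
  for (br in branches) {
    inc <- 1L
    for (l in seq_len(L)) {
      pf <- sprintf("enc_%s_l%d", br, l)
      p[[paste0(pf, "_c1_W")]] <- glorotConv(3L, inc, ch[l])
      p[[paste0(pf, "_c1_b")]] <- numeric(ch[l])
      p[[paste0(pf, "_c2_W")]] <- glorotConv(3L, ch[l], ch[l])
      p[[paste0(pf, "_c2_b")]] <- numeric(ch[l])
      inc <- ch[l]
    }
  }
  if (cfg@fusion == "dual") {
    for (l in seq_len(L)) {
      p[[sprintf("fuse_l%d_wx", l)]] <- 1
      p[[sprintf("fuse_l%d_wy", l)]] <- 1
    }
  }
  cb <- base * 2L^L
  p[["bot_c1_W"]] <- glorotConv(3L, ch[L], cb)
  p[["bot_c1_b"]] <- numeric(cb)
  p[["bot_c2_W"]] <- glorotConv(3L, cb, cb)
  p[["bot_c2_b"]] <- numeric(cb)
  for (l in rev(seq_len(L))) {
    upin <- if (l == L) cb else ch[l + 1L]
    pf <- sprintf("dec_l%d", l)
    p[[paste0(pf, "_up_W")]] <- glorotConv(2L, upin, ch[l])
    p[[paste0(pf, "_up_b")]] <- numeric(ch[l])
    p[[paste0(pf, "_c1_W")]] <- glorotConv(3L, 2L * ch[l], ch[l])
    p[[paste0(pf, "_c1_b")]] <- numeric(ch[l])
    p[[paste0(pf, "_c2_W")]] <- glorotConv(3L, ch[l], ch[l])
    p[[paste0(pf, "_c2_b")]] <- numeric(ch[l])
  }
  p[["out_W"]] <- glorotConv(1L, base, 1L)
  p[["out_b"]] <- numeric(1L)
  p
}

#' Build the dual-branch DBU-Net
#'
#' Constructs a dual-encoder U-Net whose second branch consumes the binary
#' edge map of the input and whose branches exchange information through a
#' learnable weighted cross-fusion after every encoder level. Weights are
#' Glorot-uniform initialized; the 2 * levels fusion scalars start at 1.
#'
#' @param config A \code{\link{modelConfig}} with \code{fusion = "dual"}.
#' @param seed Integer seed for weight initialization.
#' @return A \code{UNetModel}.
#' @export
buildDBUNet <- function(config = modelConfig(fusion = "dual"), seed = 42L) {
  stopifnot(is(config, "ModelConfig"))
  if (config@fusion != "dual") stop("buildDBUNet requires fusion = 'dual'")
  new("UNetModel", config = config, params = buildParams(config, seed))
}

#' Build the single-branch GSU-Net baseline
#'
#' The vanilla U-Net on the grayscale input only: identical blocks to the
#' dual model but no edge branch and no fusion scalars.
#'
#' @param config A \code{\link{modelConfig}} with \code{fusion = "none"}.
#' @param seed Integer seed for weight initialization.
#' @return A \code{UNetModel}.
#' @export
buildGSUNet <- function(config = modelConfig(fusion = "none"), seed = 42L) {
  stopifnot(is(config, "ModelConfig"))
  if (config@fusion != "none") stop("buildGSUNet requires fusion = 'none'")
  new("UNetModel", config = config, params = buildParams(config, seed))
}

#' Weighted cross-fusion of two feature maps
#'
#' Both outputs are computed from the pre-update inputs:
#' \code{fx' = fx + (wx * fx + wy * fy)} and
#' \code{fy' = fy + (wx * fx + wy * fy)}. The residual terms preserve each
#' branch's identity; with \code{wx = wy = 0} the fusion is the identity on
#' both branches.
#'
#' @param fx,fy Numeric arrays of identical shape.
#' @param wx,wy Scalar fusion weights.
#' @return List with updated \code{fx} and \code{fy}.
#' @export
fuseFeatures <- function(fx, fy, wx, wy) {
  if (!identical(dim(fx), dim(fy)) || length(fx) != length(fy))
    stop("fx and fy shapes differ")
  s <- as.numeric(wx) * fx + as.numeric(wy) * fy
  list(fx = fx + s, fy = fy + s)
}

blockForward <- function(x, p, pf) {
  c1 <- convForward(x, p[[paste0(pf, "_c1_W")]], p[[paste0(pf, "_c1_b")]])
  a1 <- reluForward(c1$y)
  c2 <- convForward(a1, p[[paste0(pf, "_c2_W")]], p[[paste0(pf, "_c2_b")]])
  a2 <- reluForward(c2$y)
  list(y = a2, cache = list(c1 = c1$cache, z1 = c1$y, c2 = c2$cache,
                            z2 = c2$y))
}

blockBackward <- function(dy, p, pf, cache) {
  g <- list()
  dz2 <- reluBackward(dy, cache$z2)
  b2 <- convBackward(dz2, p[[paste0(pf, "_c2_W")]], cache$c2)
  g[[paste0(pf, "_c2_W")]] <- b2$dW
  g[[paste0(pf, "_c2_b")]] <- b2$db
  dz1 <- reluBackward(b2$dx, cache$z1)
  b1 <- convBackward(dz1, p[[paste0(pf, "_c1_W")]], cache$c1)
  g[[paste0(pf, "_c1_W")]] <- b1$dW
  g[[paste0(pf, "_c1_b")]] <- b1$db
  list(dx = b1$dx, grads = g)
}

# Full forward pass. Returns the probability map plus every cache needed by
# modelBackward. Dropout is sampled from the current RNG stream iff train.
# Inputs arrive in the public (H, W, 1, B) convention; internally the
# channel-last (H, W, B, C) layout is used, which is layout-identical for a
# singleton channel, so entry and exit only relabel dims.
modelForward <- function(model, gray, edge = NULL, train = FALSE) {
  cfg <- model@config
  p <- model@params
  L <- cfg@levels
  dual <- cfg@fusion == "dual"
  if (dual && is.null(edge)) stop("dual model needs the edge-map input")
  d <- dim(gray)
  dim(gray) <- c(d[1], d[2], d[4], 1L)
  if (!is.null(edge)) dim(edge) <- c(d[1], d[2], d[4], 1L)
  enc <- vector("list", L)
  skips <- vector("list", L)
  hx <- gray; hy <- if (dual) edge else NULL
  for (l in seq_len(L)) {
    bx <- blockForward(hx, p, sprintf("enc_x_l%d", l))
    skips[[l]] <- bx$y
    mx <- maxpoolForward(bx$y)
    dox <- dropoutForward(mx$y, cfg@dropoutRate, train)
    lvl <- list(bx = bx$cache, mx = mx$cache, dox = dox$cache)
    if (dual) {
      by <- blockForward(hy, p, sprintf("enc_y_l%d", l))
      my <- maxpoolForward(by$y)
      doy <- dropoutForward(my$y, cfg@dropoutRate, train)
      px <- dox$y; py <- doy$y
      wx <- as.numeric(p[[sprintf("fuse_l%d_wx", l)]])
      wy <- as.numeric(p[[sprintf("fuse_l%d_wy", l)]])
      s <- wx * px + wy * py
      hx <- px + s
      hy <- py + s
      lvl <- c(lvl, list(by = by$cache, my = my$cache, doy = doy$cache,
                         px = px, py = py))
    } else {
      hx <- dox$y
    }
    enc[[l]] <- lvl
  }
  bot <- blockForward(hx, p, "bot")
  h <- bot$y
  dec <- vector("list", L)
  for (l in rev(seq_len(L))) {
    up <- upsampleForward(h)
    pf <- sprintf("dec_l%d", l)
    uc <- convForward(up$y, p[[paste0(pf, "_up_W")]], p[[paste0(pf, "_up_b")]])
    cat2 <- concatChannels(uc$y, skips[[l]])
    db <- blockForward(cat2, p, pf)
    dec[[l]] <- list(up = up$cache, uc = uc$cache, db = db$cache,
                     nUp = dim(uc$y)[4])
    h <- db$y
  }
  oc <- convForward(h, p[["out_W"]], p[["out_b"]])
  prob <- sigmoid(oc$y)
  dInt <- dim(prob)
  dim(prob) <- c(d[1], d[2], 1L, d[4])
  list(prob = prob,
       caches = list(enc = enc, dec = dec, bot = bot$cache, oc = oc$cache,
                     prob = prob, dimInt = dInt))
}

# Backward pass from dL/dprob; returns the named gradient list.
modelBackward <- function(model, caches, dprob) {
  cfg <- model@config
  p <- model@params
  L <- cfg@levels
  dual <- cfg@fusion == "dual"
  grads <- list()
  prob <- caches$prob
  dz <- dprob * prob * (1 - prob)
  dim(dz) <- caches$dimInt
  ob <- convBackward(dz, p[["out_W"]], caches$oc)
  grads[["out_W"]] <- ob$dW
  grads[["out_b"]] <- ob$db
  dh <- ob$dx
  dskips <- vector("list", L)
  for (l in seq_len(L)) {
    pf <- sprintf("dec_l%d", l)
    dcc <- caches$dec[[l]]
    bb <- blockBackward(dh, p, pf, dcc$db)
    grads <- c(grads, bb$grads)
    sp <- splitChannels(bb$dx, dcc$nUp)
    dskips[[l]] <- sp$b
    ub <- convBackward(sp$a, p[[paste0(pf, "_up_W")]], dcc$uc)
    grads[[paste0(pf, "_up_W")]] <- ub$dW
    grads[[paste0(pf, "_up_b")]] <- ub$db
    dh <- upsampleBackward(ub$dx, dcc$up)
  }
  bb <- blockBackward(dh, p, "bot", caches$bot)
  grads <- c(grads, bb$grads)
  dhx <- bb$dx
  dhy <- NULL
  for (l in rev(seq_len(L))) {
    lvl <- caches$enc[[l]]
    if (dual) {
      wx <- as.numeric(p[[sprintf("fuse_l%d_wx", l)]])
      wy <- as.numeric(p[[sprintf("fuse_l%d_wy", l)]])
      if (is.null(dhy)) dhy <- array(0, dim(dhx))
      ds <- dhx + dhy
      grads[[sprintf("fuse_l%d_wx", l)]] <- sum(ds * lvl$px)
      grads[[sprintf("fuse_l%d_wy", l)]] <- sum(ds * lvl$py)
      dpx <- dhx + wx * ds
      dpy <- dhy + wy * ds
      dmy <- maxpoolBackward(dropoutBackward(dpy, lvl$doy), lvl$my)
      by <- blockBackward(dmy, p, sprintf("enc_y_l%d", l), lvl$by)
      grads <- c(grads, by$grads)
      dhyNext <- by$dx
    } else {
      dpx <- dhx
      dhyNext <- NULL
    }
    dmx <- maxpoolBackward(dropoutBackward(dpx, lvl$dox), lvl$mx) +
      dskips[[l]]
    bx <- blockBackward(dmx, p, sprintf("enc_x_l%d", l), lvl$bx)
    grads <- c(grads, bx$grads)
    dhx <- bx$dx
    dhy <- dhyNext
  }
  grads
}

#' Forward pass: predicted probability map
#'
#' Runs the network in evaluation mode (dropout inactive).
#'
#' @param model A \code{UNetModel}.
#' @param gray Grayscale input, array (H, W, 1, B) or matrix (H, W).
#' @param edge Edge-map input for dual models (same shape rules); computed
#'   from \code{gray} with the Roberts pipeline when omitted.
#' @return Probability array (H, W, 1, B), values in (0, 1).
#' @export
predictProb <- function(model, gray, edge = NULL) {
  gray <- asBatch(gray)
  if (model@config@fusion == "dual") {
    if (is.null(edge)) {
      edge <- gray
      for (i in seq_len(dim(gray)[4]))
        edge[, , 1, i] <- edgeImage(gray[, , 1, i], "roberts")
    } else edge <- asBatch(edge)
  } else edge <- NULL
  modelForward(model, gray, edge, train = FALSE)$prob
}

asBatch <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L, 1L))
  else if (length(dim(x)) == 4L) x
  else stop("input must be a matrix or an (H, W, 1, B) array")
}

#' Loss and parameter gradients on one batch
#'
#' Computes the training loss (hybrid focal + dice, or dice alone) on a batch
#' and backpropagates it through the network. Mainly useful for inspecting
#' gradient flow, e.g. checking that every fusion scalar is learnable.
#'
#' @param model A \code{UNetModel}.
#' @param gray,edge,mask Batch arrays (H, W, 1, B); \code{edge} may be NULL
#'   for single-branch models.
#' @param lossCfg A \code{\link{lossConfig}}.
#' @param loss "hybrid" or "dice".
#' @param train Logical; sample dropout masks (TRUE) or run deterministic.
#' @return List with scalar \code{loss} and named list \code{grads}.
#' @export
modelGradients <- function(model, gray, mask, edge = NULL,
                           lossCfg = lossConfig(),
                           loss = c("hybrid", "dice"), train = TRUE) {
  loss <- match.arg(loss)
  fw <- modelForward(model, gray, edge, train = train)
  B <- dim(gray)[4]
  lv <- 0
  dprob <- array(0, dim(fw$prob))
  for (i in seq_len(B)) {
    pi <- fw$prob[, , 1, i]
    ti <- mask[, , 1, i]
    if (loss == "hybrid") {
      lv <- lv + hybridLoss(pi, ti, lossCfg)
      dprob[, , 1, i] <- hybridLossGrad(pi, ti, lossCfg) / B
    } else {
      lv <- lv + diceLoss(pi, ti, lossCfg@smooth)
      dprob[, , 1, i] <- diceLossGrad(pi, ti, lossCfg@smooth) / B
    }
  }
  list(loss = lv / B, grads = modelBackward(model, fw$caches, dprob))
}
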