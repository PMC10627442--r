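# Synthetic breast-ultrasound-like phantoms.
#
# Speckle is modeled as Gaussian-smoothed multiplicative exponential noise (a
# standard surrogate for the granular interference pattern of coherent
# ultrasound); the lesion is a hypoechoic (darkened) ellipse whose boundary
# is radially jittered by a few random Fourier harmonics and then blurred,
# giving the fuzzy margins that make these images hard to segment. The
# ground-truth mask is the un-blurred lesion support.

phantomSeed <- function(seed, index) {
  as.integer((abs(seed) %% 1000003L) * 2011L + index %% 100003L)
}

smoothField <- function(m, sigma) {
  if (sigma <= 0) return(m)
  matrix(EBImage::imageData(EBImage::gblur(m, sigma = sigma)),
         nrow(m), ncol(m))
}

#' Generate one synthetic phantom
#'
#' Deterministic in \code{(cfg@seed, index)}. The lesion darkening factor is
#' \code{1 - intensityDrop}; malignant-labelled phantoms (drawn with the
#' benchmark's benign/malignant proportion, about 2:1) get 2.5x the boundary
#' jitter of benign ones, purely so class stratification has something to
#' stratify. With probability \code{multiMaskProb} the mask is emitted as two
#' overlapping column-split components whose union is the true mask.
#'
#' @param cfg A \code{\link{phantomConfig}}.
#' @param index Phantom index (>= 1).
#' @return List with \code{image} (matrix in [0, 1]), \code{masks} (list of
#'   one or two binary matrices), \code{class} ("benign"/"malignant") and
#'   \code{truth} (lesion center, semi-axes, angle, pixel area).
#' @export
generatePhantom <- function(cfg, index) {
  stopifnot(is(cfg, "PhantomConfig"), index >= 1)
  set.seed(phantomSeed(cfg@seed, index))
  H <- cfg@size[1]; W <- cfg@size[2]
  amax <- max(cfg@lesionAxesRange)
  margin <- amax * 1.35 + 2
  if (2 * margin >= min(H, W)) stop("lesion cannot fit inside the image")
  cls <- if (stats::runif(1) < 210 / 647) "malignant" else "benign"
  jit <- cfg@boundaryJitter * if (cls == "malignant") 2.5 else 1
  cy <- stats::runif(1, margin, H - margin)
  cx <- stats::runif(1, margin, W - margin)
  ax <- stats::runif(2, cfg@lesionAxesRange[1], cfg@lesionAxesRange[2])
  ang <- stats::runif(1, 0, pi)
  harm <- 2:4
  coef <- stats::runif(length(harm), -1, 1)
  phase <- stats::runif(length(harm), 0, 2 * pi)

  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- (cos(ang) * xx + sin(ang) * yy) / ax[1]
  v <- (-sin(ang) * xx + cos(ang) * yy) / ax[2]
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  pert <- matrix(0, H, W)
  for (i in seq_along(harm))
    pert <- pert + coef[i] * cos(harm[i] * theta + phase[i])
  pert <- jit * pert / length(harm)
  mask <- (rho <= 1 + pert) * 1

  tissue <- 0.55
  intens <- matrix(tissue, H, W)
  intens[mask == 1] <- tissue * (1 - cfg@intensityDrop)
  intens <- smoothField(intens, cfg@blurSigma)
  speckle <- smoothField(matrix(stats::rexp(H * W), H, W), 1)
  speckle <- speckle / mean(speckle)
  img <- intens * ((1 - cfg@speckleScale) + cfg@speckleScale * speckle)
  img <- pmin(pmax(img, 0), 1)

  masks <- list(mask)
  if (stats::runif(1) < cfg@multiMaskProb) {
    cols <- which(colSums(mask) > 0)
    if (length(cols) >= 6) {
      mid <- cols[ceiling(length(cols) / 2)]
      m1 <- mask; m1[, seq_len(W) > mid + 2] <- 0
      m2 <- mask; m2[, seq_len(W) < mid - 2] <- 0
      if (sum(m1) > 0 && sum(m2) > 0) masks <- list(m1, m2)
    }
  }
  list(image = img, masks = masks, class = cls,
       truth = list(center = c(cy, cx), axes = ax, angle = ang,
                    area = sum(mask)))
}

#' Generate an in-memory phantom dataset
#'
#' Convenience wrapper producing the arrays consumed by the trainer directly
#' (no disk round trip): grayscale images, edge maps and merged masks.
#'
#' @param n Number of phantoms.
#' @param cfg A \code{\link{phantomConfig}}.
#' @param operator Edge operator for the edge-map channel.
#' @param offset Index offset (phantom i uses index \code{offset + i}).
#' @return List with \code{gray}, \code{edge}, \code{mask} arrays
#'   (H, W, 1, n), \code{id}, \code{class}.
#' @export
phantomDataset <- function(n, cfg = phantomConfig(), operator = "roberts",
                           offset = 0L) {
  H <- cfg@size[1]; W <- cfg@size[2]
  gray <- array(0, c(H, W, 1, n))
  edge <- array(0, c(H, W, 1, n))
  mask <- array(0, c(H, W, 1, n))
  cls <- character(n)
  for (i in seq_len(n)) {
    ph <- generatePhantom(cfg, offset + i)
    gray[, , 1, i] <- ph$image
    edge[, , 1, i] <- edgeImage(ph$image, operator)
    mask[, , 1, i] <- mergeMasks(ph$masks)
    cls[i] <- ph$class
  }
  list(gray = gray, edge = edge, mask = mask,
       id = sprintf("phantom_%04d", offset + seq_len(n)), class = cls)
}

#' Write a BUSI-style phantom dataset to disk
#'
#' Emits per-class folders with \code{<stem>.png} images and
#' \code{<stem>_mask.png} (plus \code{_mask_1.png} for split cases) binary
#' masks, consumable unchanged by \code{\link{indexDataset}}, together with a
#' \code{manifest.csv} holding the ground-truth lesion parameters.
#'
#' @param n Number of phantoms.
#' @param cfg A \code{\link{phantomConfig}}.
#' @param outDir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
generateDataset <- function(n, cfg = phantomConfig(), outDir) {
  stopifnot(n >= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generatePhantom(cfg, i)
    d <- file.path(outDir, ph$class)
    dir.create(d, showWarnings = FALSE)
    stem <- sprintf("%s_%03d", ph$class, i)
    png::writePNG(ph$image, file.path(d, paste0(stem, ".png")))
    for (k in seq_along(ph$masks)) {
      suffix <- if (k == 1) "_mask" else sprintf("_mask_%d", k - 1)
      png::writePNG(ph$masks[[k]], file.path(d, paste0(stem, suffix, ".png")))
    }
    rows[[i]] <- data.frame(id = file.path(ph$class, stem),
      class = ph$class, n_masks = length(ph$masks),
      center_y = ph$truth$center[1], center_x = ph$truth$center[2],
      axis_a = ph$truth$axes[1], axis_b = ph$truth$axes[2],
      angle = ph$truth$angle, area = ph$truth$area,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
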