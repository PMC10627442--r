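#' Load a PNG as a grayscale intensity matrix on the 0-255 scale
#'
#' 8-bit grayscale PNGs map byte b to intensity b; RGB(A) PNGs are converted
#' by arithmetic averaging of the three color channels.
#'
#' @param path Path to a PNG file.
#' @return 2-D numeric matrix with values in [0, 255].
#' @export
loadGrayscale <- function(path) {
  if (!file.exists(path)) stop("cannot read image, no such file: ", path)
  img <- tryCatch(png::readPNG(path),
    error = function(e) stop("not a readable PNG: ", path, " (", conditionMessage(e), ")"))
  if (length(dim(img)) == 3L)
    img <- matrix((img[, , 1] + img[, , 2] + img[, , 3]) / 3,
                  dim(img)[1], dim(img)[2])
  img * 255
}

#' Normalize a 0-255 intensity image to [0, 1]
#'
#' Divides every pixel by 255 (the maximum possible 8-bit value).
#'
#' @param raw 2-D numeric matrix with values in [0, 255].
#' @return Matrix with values in [0, 1].
#' @export
normalizeImage <- function(raw) {
  if (any(raw < 0) || any(raw > 255))
    stop("pixel values outside [0, 255]")
  raw / 255
}

#' Map a [0, 1] image back to the 0-255 scale
#' @param img Matrix with values in [0, 1].
#' @return Matrix with values in [0, 255].
#' @export
denormalizeImage <- function(img) img * 255

#' Resize an image/mask pair to a common target size
#'
#' The intensity image is interpolated bilinearly; the mask uses
#' nearest-neighbor so it stays strictly binary.
#'
#' @param image 2-D numeric matrix.
#' @param mask 2-D binary matrix of the same shape.
#' @param target Integer length-2 (H, W), default \code{c(256, 256)}.
#' @return List with resized \code{image} and \code{mask}.
#' @export
resizePair <- function(image, mask, target = c(256L, 256L)) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ")
  if (any(target < 1)) stop("target size must be positive")
  list(
    image = resizeBilinear(image, target[1], target[2]),
    mask = resizeNearest(mask, target[1], target[2])
  )
}

# EBImage stores the first array dimension as x; passing our row-major
# matrices with w = H keeps (rows, cols) intact because resize is separable.
resizeBilinear <- function(m, H, W) {
  matrix(EBImage::imageData(
    EBImage::resize(m, w = H, h = W, filter = "bilinear")), H, W)
}

resizeNearest <- function(m, H, W) {
  matrix(EBImage::imageData(
    EBImage::resize(m, w = H, h = W, filter = "none")), H, W)
}

#' Merge multiple ground-truth masks into one
#'
#' Pixelwise union (logical OR). Used for the benchmark's multi-mask cases
#' where one image has several disjoint or overlapping lesion annotations.
#'
#' @param masks Non-empty list of binary matrices of identical shape.
#' @return Binary matrix, the union of all inputs.
#' @export
mergeMasks <- function(masks) {
  if (!is.list(masks) || length(masks) == 0)
    stop("mergeMasks needs a non-empty list of masks")
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d))
    stop("masks differ in shape")
  out <- Reduce(`+`, masks)
  (out > 0) * 1
}

#' Index a BUSI-style image/mask directory tree
#'
#' Expects per-class folders (\code{benign/}, \code{malignant/}) whose PNG
#' files follow the \code{<stem>.png} / \code{<stem>_mask*.png} convention.
#' Images without any mask are skipped (the benchmark's normal class has no
#' masks and is excluded from the segmentation task).
#'
#' @param root Dataset root directory.
#' @param classes Class folder names to index.
#' @return data.frame with columns \code{id} (relative path stem),
#'   \code{image_path}, \code{mask_paths} (semicolon-joined), \code{class}.
#' @export
indexDataset <- function(root, classes = c("benign", "malignant")) {
  if (!dir.exists(root)) stop("no such dataset root: ", root)
  rows <- list()
  for (cl in classes) {
    d <- file.path(root, cl)
    if (!dir.exists(d)) next
    pngs <- list.files(d, pattern = "\\.png$", full.names = FALSE)
    imgs <- pngs[!grepl("_mask", pngs)]
    for (f in imgs) {
      stem <- sub("\\.png$", "", f)
      masks <- sort(list.files(d,
        pattern = paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", stem),
                         "_mask.*\\.png$"),
        full.names = TRUE))
      if (length(masks) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        id = file.path(cl, stem),
        image_path = file.path(d, f),
        mask_paths = paste(masks, collapse = ";"),
        class = cl,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no image/mask pairs found under ", root)
  do.call(rbind, rows)
}

#' Load and preprocess an indexed dataset
#'
#' For every manifest row: load the grayscale image, merge its masks (union,
#' before any resizing so component boundaries cannot acquire interpolation
#' seams), resize the pair to \code{target}, normalize the image to [0, 1],
#' and compute the edge map with the requested operator.
#'
#' @param manifest data.frame from \code{\link{indexDataset}}.
#' @param target Integer (H, W) target size.
#' @param operator Edge operator for the second encoder branch.
#' @return List with \code{gray}, \code{edge}, \code{mask} arrays of shape
#'   (H, W, 1, n), plus \code{id} and \code{class} vectors.
#' @export
loadDataset <- function(manifest, target = c(256L, 256L),
                        operator = "roberts") {
  n <- nrow(manifest)
  H <- target[1]; W <- target[2]
  gray <- array(0, c(H, W, 1, n))
  edge <- array(0, c(H, W, 1, n))
  mask <- array(0, c(H, W, 1, n))
  for (i in seq_len(n)) {
    raw <- loadGrayscale(manifest$image_path[i])
    mpaths <- strsplit(manifest$mask_paths[i], ";", fixed = TRUE)[[1]]
    m <- mergeMasks(lapply(mpaths, function(p)
      (loadGrayscale(p) > 127.5) * 1))
    rp <- resizePair(raw, m, target)
    g <- normalizeImage(rp$image)
    gray[, , 1, i] <- g
    edge[, , 1, i] <- edgeImage(g, operator)
    mask[, , 1, i] <- rp$mask
  }
  list(gray = gray, edge = edge, mask = mask,
       id = manifest$id, class = manifest$class)
}

#' Stratified k-fold split
#'
#' Assigns every sample to exactly one test fold, stratified by class label
#' so each fold's class proportions stay within one sample of the global
#' proportions. Deterministic for a fixed seed.
#'
#' @param ids Character vector of sample identifiers.
#' @param classes Class label per sample.
#' @param k Number of folds (default 5).
#' @param seed Integer seed (default 42).
#' @return data.frame with columns \code{id}, \code{class}, \code{fold}.
#' @export
makeFolds <- function(ids, classes, k = 5L, seed = 42L) {
  n <- length(ids)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("more folds than samples")
  if (length(classes) != n) stop("ids and classes lengths differ")
  fold <- integer(n)
  set.seed(as.integer(seed))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  data.frame(id = ids, class = classes, fold = fold,
             stringsAsFactors = FALSE)
}

#' Train/test ids of one fold
#' @param folds data.frame from \code{\link{makeFolds}}.
#' @param foldIndex Which fold serves as the test set.
#' @return List with character vectors \code{train} and \code{test}.
#' @export
foldSplit <- function(folds, foldIndex) {
  stopifnot(foldIndex %in% folds$fold)
  list(train = folds$id[folds$fold != foldIndex],
       test = folds$id[folds$fold == foldIndex])
}
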