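#' Edge-operator kernel pairs
#'
#' Returns the x/y kernel pair for one of the supported edge operators. The
#' Roberts cross pair is the 2x2 diagonal-differencing pair
#' \code{dx = [[+1, 0], [0, -1]]}, \code{dy = [[0, +1], [-1, 0]]}; Prewitt and
#' Sobel are the textbook 3x3 pairs with the y kernel equal to the transpose
#' of the x kernel.
#'
#' @param operator One of "roberts", "prewitt", "sobel".
#' @return List with 2-D numeric matrices \code{x} and \code{y}.
#' @examples
#' edgeKernels("roberts")$x
#' @export
edgeKernels <- function(operator = c("roberts", "prewitt", "sobel")) {
  operator <- match.arg(operator)
  switch(operator,
    roberts = list(
      x = matrix(c(1, 0, 0, -1), 2, 2, byrow = TRUE),
      y = matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE)),
    prewitt = {
      kx <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3, byrow = TRUE)
      list(x = kx, y = t(kx))
    },
    sobel = {
      kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
      list(x = kx, y = t(kx))
    })
}

#' Valid cross-correlation of an image with a small kernel
#'
#' Correlation convention with the kernel anchored at its top-left:
#' \code{out[i, j] = sum_ab kernel[a, b] * image[i + a - 1, j + b - 1]}.
#' Output shape is \code{(H - h + 1, W - w + 1)} for an \code{h x w} kernel.
#'
#' @param image 2-D numeric matrix.
#' @param kernel 2-D numeric matrix no larger than \code{image}.
#' @return 2-D numeric matrix of the valid correlation.
#' @export
convolveValid <- function(image, kernel) {
  if (!is.matrix(image) || !is.matrix(kernel))
    stop("image and kernel must be matrices")
  H <- nrow(image); W <- ncol(image)
  h <- nrow(kernel); w <- ncol(kernel)
  if (h > H || w > W)
    stop(sprintf("kernel (%dx%d) larger than image (%dx%d)", h, w, H, W))
  out <- matrix(0, H - h + 1L, W - w + 1L)
  for (a in seq_len(h)) for (b in seq_len(w)) {
    if (kernel[a, b] == 0) next
    out <- out + kernel[a, b] *
      image[a:(a + H - h), b:(b + W - w), drop = FALSE]
  }
  out
}

#' Gradient field of an image under an edge-operator pair
#'
#' Convolves the image with the operator's x and y kernels (valid
#' correlation), forms the l2 gradient magnitude
#' \code{G = sqrt(Gx^2 + Gy^2)}, and the scalar threshold \code{th} as the
#' arithmetic mean of the magnitude over all its entries.
#'
#' @param image 2-D numeric matrix, at least as large as the kernels.
#' @param operator One of "roberts", "prewitt", "sobel".
#' @return List with matrices \code{gx}, \code{gy}, \code{magnitude} and the
#'   scalar \code{threshold}.
#' @examples
#' f <- gradientField(matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, 3), "roberts")
#' f$threshold  # sqrt(2) / 2 for the vertical unit step
#' @export
gradientField <- function(image, operator = c("roberts", "prewitt", "sobel")) {
  operator <- match.arg(operator)
  ks <- edgeKernels(operator)
  if (nrow(image) < nrow(ks$x) || ncol(image) < ncol(ks$x))
    stop(sprintf("image (%dx%d) smaller than the %dx%d kernel",
                 nrow(image), ncol(image), nrow(ks$x), ncol(ks$x)))
  gx <- convolveValid(image, ks$x)
  gy <- convolveValid(image, ks$y)
  magnitude <- sqrt(gx^2 + gy^2)
  list(gx = gx, gy = gy, magnitude = magnitude,
       threshold = mean(magnitude))
}

#' Roberts gradient field
#'
#' Convenience wrapper for \code{gradientField(image, "roberts")}.
#'
#' @inheritParams gradientField
#' @return See \code{\link{gradientField}}.
#' @export
robertsGradients <- function(image) gradientField(image, "roberts")

#' Binarize a gradient field at its mean-magnitude threshold
#'
#' A pixel is an edge pixel (1) iff its gradient magnitude strictly exceeds
#' the field's threshold; ties and sub-threshold pixels map to background (0).
#'
#' @param field A gradient field as returned by \code{\link{gradientField}}.
#' @return 2-D matrix in \{0, 1\}.
#' @export
binarizeGradient <- function(field) {
  stopifnot(is.list(field), !is.null(field$magnitude), !is.null(field$threshold))
  (field$magnitude > field$threshold) * 1
}

# Replicate-pad so that a subsequent valid correlation with a k x k kernel
# anchored top-left returns the original image size. For k = 2 only the
# bottom/right borders are extended; for k = 3 all four borders grow by 1.
padReplicate <- function(image, k) {
  pt <- (k - 1L) %/% 2L
  pb <- (k - 1L) - pt
  H <- nrow(image); W <- ncol(image)
  ri <- c(rep(1L, pt), seq_len(H), rep(H, pb))
  ci <- c(rep(1L, pt), seq_len(W), rep(W, pb))
  image[ri, ci, drop = FALSE]
}

#' Full edge-image pipeline
#'
#' Replicate-pads the (preprocessed, [0,1]-valued) image so output size equals
#' input size, computes the operator's gradient magnitude, thresholds at the
#' mean magnitude, and returns the strict binarization. This is the binary
#' edge map fed to the second encoder branch of the dual-branch network.
#'
#' @param image 2-D numeric matrix with values in [0, 1].
#' @param operator One of "roberts", "prewitt", "sobel".
#' @return 2-D matrix in \{0, 1\}, same shape as \code{image}.
#' @examples
#' img <- matrix(0, 16, 16); img[5:12, 5:12] <- 1
#' sum(edgeImage(img, "roberts"))  # a ring of edge pixels around the box
#' @export
edgeImage <- function(image, operator = c("roberts", "prewitt", "sobel")) {
  operator <- match.arg(operator)
  k <- if (operator == "roberts") 2L else 3L
  field <- gradientField(padReplicate(image, k), operator)
  binarizeGradient(field)
}
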