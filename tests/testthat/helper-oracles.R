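# Independent oracles and shared fixtures.

# quadruple-loop valid correlation, deliberately naive
naiveConvolveValid <- function(image, kernel) {
  H <- nrow(image); W <- ncol(image)
  h <- nrow(kernel); w <- ncol(kernel)
  out <- matrix(0, H - h + 1, W - w + 1)
  for (i in seq_len(H - h + 1)) for (j in seq_len(W - w + 1)) {
    s <- 0
    for (a in seq_len(h)) for (b in seq_len(w))
      s <- s + kernel[a, b] * image[i + a - 1, j + b - 1]
    out[i, j] <- s
  }
  out
}

# mean binary cross-entropy with the same clipping as the focal loss
naiveBCE <- function(prob, target) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

# tiny architecture used across the model tests
tinyModelConfig <- function(fusion = "dual") {
  modelConfig(levels = 2L, baseChannels = 8L, dropoutRate = 0.2,
              inputSize = c(32L, 32L), fusion = fusion)
}

# small phantom preset (desk scale)
tinyPhantomConfig <- function(seed = 11L, size = 64L) {
  phantomConfig(size = c(size, size),
                lesionAxesRange = c(0.09 * size, 0.22 * size), seed = seed)
}

randomMask <- function(H, W, p = 0.3) {
  matrix(as.numeric(rbinom(H * W, 1, p)), H, W)
}

# vertical unit-step image of the worked Roberts example
stepImage3 <- function() matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, 3,
                                byrow = TRUE)
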