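# Trainable-network primitives.
#
# Feature maps are numeric arrays of shape (H, W, B, C): channel LAST, so
# that flattening to the (H*W*B x C) matrix a BLAS product needs is a plain
# reshape with no permutation. Convolutions use same-padding, stride 1,
# correlation convention; each k x k kernel offset contributes one
# (H*W*B x Cin) %*% (Cin x Cout) dgemm. Asymmetric padding for even kernels
# pads only bottom/right, matching the top-left anchor used by the edge
# filters. Arrays with a singleton channel are layout-identical to the
# user-facing (H, W, 1, B) convention.

fmapToMat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

# kernel array (k, k, Ci, Co) -> (k*k*Ci, Co) matrix whose row order matches
# the im2col column order (ci fastest, then kernel column, then kernel row)
flattenKernel <- function(W4) {
  d <- dim(W4)
  matrix(aperm(W4, c(3, 2, 1, 4)), d[1] * d[2] * d[3], d[4])
}

unflattenKernel <- function(Wm, k, Ci, Co) {
  aperm(array(Wm, c(Ci, k, k, Co)), c(3, 2, 1, 4))
}

convForward <- function(x, W4, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; B <- d[3]; Ci <- d[4]
  k <- dim(W4)[1]; Co <- dim(W4)[4]
  if (dim(W4)[3] != Ci) stop("conv channel mismatch")
  n <- H * Wd * B
  col <- if (k == 1L) fmapToMat(x) else cpp_im2col(x, H, Wd, B, Ci, k)
  y <- col %*% flattenKernel(W4) + matrix(b, n, Co, byrow = TRUE)
  dim(y) <- c(H, Wd, B, Co)
  list(y = y, cache = list(col = col, dims = d, k = k))
}

convBackward <- function(dy, W4, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; B <- d[3]; Ci <- d[4]
  k <- cache$k; Co <- dim(W4)[4]
  dymat <- fmapToMat(dy)
  db <- colSums(dymat)
  dW <- unflattenKernel(crossprod(cache$col, dymat), k, Ci, Co)
  dcol <- tcrossprod(dymat, flattenKernel(W4))
  if (k == 1L) {
    dim(dcol) <- d
    return(list(dx = dcol, dW = dW, db = db))
  }
  list(dx = cpp_col2im(dcol, H, Wd, B, Ci, k), dW = dW, db = db)
}

reluForward <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

reluBackward <- function(dy, x) dy * (x > 0)

maxpoolForward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  if (H %% 2L || W %% 2L) stop("maxpool needs even spatial dims")
  oi <- seq(1L, H, 2L); oj <- seq(1L, W, 2L)
  p11 <- x[oi, oj, , , drop = FALSE]
  p21 <- x[oi + 1L, oj, , , drop = FALSE]
  p12 <- x[oi, oj + 1L, , , drop = FALSE]
  p22 <- x[oi + 1L, oj + 1L, , , drop = FALSE]
  y <- pmax(p11, p21, p12, p22)
  list(y = y, cache = list(p11 = p11, p21 = p21, p12 = p12, p22 = p22,
                           y = y, dims = d))
}

maxpoolBackward <- function(dy, cache) {
  cc <- cache
  d11 <- (cc$p11 == cc$y) * dy
  d21 <- (cc$p21 == cc$y & cc$p11 != cc$y) * dy
  d12 <- (cc$p12 == cc$y & cc$p11 != cc$y & cc$p21 != cc$y) * dy
  d22 <- dy - d11 - d21 - d12
  d <- cc$dims
  dx <- array(0, d)
  oi <- seq(1L, d[1], 2L); oj <- seq(1L, d[2], 2L)
  dx[oi, oj, , ] <- d11
  dx[oi + 1L, oj, , ] <- d21
  dx[oi, oj + 1L, , ] <- d12
  dx[oi + 1L, oj + 1L, , ] <- d22
  dx
}

dropoutForward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, cache = mask)
}

dropoutBackward <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# 1-D bilinear interpolation matrix (nOut x nIn), half-pixel centers,
# boundary-clamped. Rows sum to 1, so constants are preserved.
bilinearMatrix <- function(nOut, nIn) {
  src <- (seq_len(nOut) - 0.5) * (nIn / nOut) - 0.5
  i0 <- floor(src); w <- src - i0
  i0c <- pmin(pmax(i0, 0), nIn - 1)
  i1c <- pmin(pmax(i0 + 1, 0), nIn - 1)
  M <- matrix(0, nOut, nIn)
  M[cbind(seq_len(nOut), i0c + 1)] <- 1 - w
  M[cbind(seq_len(nOut), i1c + 1)] <- M[cbind(seq_len(nOut), i1c + 1)] + w
  M
}

# separable linear resample: out = My %*% x %*% t(Mx) per (batch, channel)
resampleLinear <- function(x, My, Mx) {
  d <- dim(x); H <- d[1]; W <- d[2]
  H2 <- nrow(My); W2 <- nrow(Mx)
  y1 <- array(My %*% matrix(x, H, W * d[3] * d[4]), c(H2, W, d[3], d[4]))
  y2 <- Mx %*% matrix(aperm(y1, c(2, 1, 3, 4)), W, H2 * d[3] * d[4])
  aperm(array(y2, c(W2, H2, d[3], d[4])), c(2, 1, 3, 4))
}

upsampleForward <- function(x) {
  d <- dim(x)
  My <- bilinearMatrix(2L * d[1], d[1])
  Mx <- bilinearMatrix(2L * d[2], d[2])
  list(y = resampleLinear(x, My, Mx), cache = list(My = My, Mx = Mx))
}

upsampleBackward <- function(dy, cache) {
  resampleLinear(dy, t(cache$My), t(cache$Mx))
}

concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!identical(da[1:3], db[1:3]))
    stop("concat shape mismatch")
  y <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  y
}

splitChannels <- function(dy, c1) {
  d <- dim(dy)
  list(a = dy[, , , seq_len(c1), drop = FALSE],
       b = dy[, , , (c1 + 1L):d[4], drop = FALSE])
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# --- Adam -------------------------------------------------------------------

adamInit <- function(params) {
  list(
    m = lapply(params, function(p)
      array(0, if (is.null(dim(p))) length(p) else dim(p))),
    v = lapply(params, function(p)
      array(0, if (is.null(dim(p))) length(p) else dim(p))),
    t = 0L
  )
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
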