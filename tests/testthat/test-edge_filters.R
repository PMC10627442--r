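test_that("kernel pairs are the published stencils with the right symmetry", {
  rb <- edgeKernels("roberts")
  expect_identical(rb$x, matrix(c(1, 0, 0, -1), 2, 2, byrow = TRUE))
  expect_identical(rb$y, matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE))
  # the Roberts pair is related by a 90-degree rotation
  rot90 <- function(m) t(m)[, nrow(m):1]
  expect_identical(rot90(rb$x), rb$y)
  # the 3x3 pairs are related by transposition
  for (op in c("prewitt", "sobel")) {
    ks <- edgeKernels(op)
    expect_identical(t(ks$x), ks$y)
  }
  expect_error(edgeKernels("canny"))
})

test_that("valid correlation matches hand-expanded examples", {
  I <- stepImage3()
  ks <- edgeKernels("roberts")
  # Gx(i,j) = I(i,j) - I(i+1,j+1); Gy(i,j) = I(i,j+1) - I(i+1,j)
  expect_equal(convolveValid(I, ks$x), matrix(c(0, -1, 0, -1), 2, 2,
                                              byrow = TRUE))
  expect_equal(convolveValid(I, ks$y), matrix(c(0, 1, 0, 1), 2, 2,
                                              byrow = TRUE))
  expect_equal(convolveValid(I, matrix(0, 2, 2)), matrix(0, 2, 2))
  # differencing kernels annihilate constants
  expect_equal(convolveValid(matrix(3, 5, 7), ks$x), matrix(0, 4, 6))
  expect_error(convolveValid(matrix(0, 2, 2), matrix(0, 3, 3)),
               "larger than image")
})

test_that("optimized correlation equals the quadruple-loop oracle", {
  set.seed(5)
  kerns <- c(lapply(c("roberts", "prewitt", "sobel"),
                    function(o) edgeKernels(o)$x),
             list(matrix(rnorm(6), 2, 3)))
  for (i in 1:25) {
    H <- sample(8:32, 1); W <- sample(8:32, 1)
    img <- matrix(runif(H * W), H, W)
    for (k in kerns)
      expect_lt(max(abs(convolveValid(img, k) - naiveConvolveValid(img, k))),
                1e-12)
  }
})

test_that("Roberts gradient field of the vertical step is the worked example", {
  f <- robertsGradients(stepImage3())
  expect_equal(f$magnitude, matrix(c(0, sqrt(2), 0, sqrt(2)), 2, 2,
                                   byrow = TRUE))
  expect_equal(f$threshold, sqrt(2) / 2)
  expect_equal(binarizeGradient(f), matrix(c(0, 1, 0, 1), 2, 2,
                                           byrow = TRUE))
  expect_error(robertsGradients(matrix(0, 1, 1)), "smaller")
})

test_that("binarization is strict: ties go to background", {
  fconst <- robertsGradients(matrix(0.7, 4, 4))
  expect_equal(fconst$threshold, 0)
  expect_equal(binarizeGradient(fconst), matrix(0, 3, 3))
  # all magnitudes equal the mean -> nothing strictly exceeds it
  fake <- list(magnitude = matrix(2, 3, 3), threshold = 2)
  expect_equal(binarizeGradient(fake), matrix(0, 3, 3))
})

test_that("single bright pixel activates exactly the Roberts stencil support", {
  img <- matrix(0, 8, 8); img[4, 5] <- 1
  f <- robertsGradients(img)
  # I(i,j), I(i+1,j+1) for dx; I(i,j+1), I(i+1,j) for dy: 4 output positions
  expect_equal(sum(f$magnitude > 0), 4)
  expect_setequal(which(f$magnitude > 0),
                  c(which(outer(1:7, 1:7, function(i, j)
                    (i %in% 3:4) & (j %in% 4:5)))))
})

test_that("full pipeline preserves shape and rings a sharp box", {
  img <- matrix(0.2, 16, 16); img[5:12, 5:12] <- 0.9
  for (op in c("roberts", "prewitt", "sobel")) {
    e <- edgeImage(img, op)
    expect_identical(dim(e), c(16L, 16L))
    expect_true(all(e %in% c(0, 1)))
    # interior of the box and far background are non-edge
    expect_equal(sum(e[7:10, 7:10]), 0)
    expect_equal(sum(e[1:2, 1:2]), 0)
    # the boundary band contains edge pixels
    expect_gt(sum(e[4:13, 4:13]) - sum(e[6:11, 6:11]), 0)
  }
  expect_equal(edgeImage(matrix(0.5, 10, 10), "roberts"), matrix(0, 10, 10))
  expect_error(edgeImage(img, "laplacian"))
})

test_that("gradient scale covariance and rotation covariance hold", {
  set.seed(9)
  img <- matrix(runif(144), 12, 12)
  f <- robertsGradients(img)
  for (c in c(0.5, 3)) {
    fc <- robertsGradients(c * img)
    expect_equal(fc$magnitude, c * f$magnitude, tolerance = 1e-12)
    expect_equal(fc$threshold, c * f$threshold, tolerance = 1e-12)
    expect_equal(binarizeGradient(fc), binarizeGradient(f))
  }
  # transposition maps each Roberts gradient to (+/-) its own transpose;
  # a 90-degree rotation swaps the roles of the two gradients
  ft <- robertsGradients(t(img))
  expect_equal(ft$gx, t(f$gx), tolerance = 1e-12)
  expect_equal(ft$gy, -t(f$gy), tolerance = 1e-12)
  rot90 <- function(m) t(m)[, nrow(m):1]
  fr <- robertsGradients(rot90(img))
  expect_equal(abs(fr$gx), rot90(abs(f$gy)), tolerance = 1e-12)
  expect_equal(abs(fr$gy), rot90(abs(f$gx)), tolerance = 1e-12)
})
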