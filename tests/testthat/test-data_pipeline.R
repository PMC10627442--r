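test_that("PNG loading recovers 8-bit gray values and averages RGB channels", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "white.png")
  png::writePNG(matrix(1, 2, 2), f1)
  expect_equal(loadGrayscale(f1), matrix(255, 2, 2))
  f2 <- file.path(d, "rgb.png")
  png::writePNG(array(c(30, 60, 90) / 255, c(1, 1, 3)), f2)
  expect_equal(loadGrayscale(f2), matrix(60, 1, 1))
  f3 <- file.path(d, "zero.png")
  png::writePNG(matrix(0, 1, 1), f3)
  expect_equal(loadGrayscale(f3), matrix(0, 1, 1))
  expect_error(loadGrayscale(file.path(d, "missing.png")), "missing.png")
  f4 <- file.path(d, "junk.png")
  writeLines("not a png", f4)
  expect_error(loadGrayscale(f4), "PNG")
})

test_that("normalization is exact division by 255 and round-trips", {
  expect_equal(normalizeImage(matrix(255, 1, 1)), matrix(1, 1, 1))
  expect_equal(normalizeImage(matrix(0, 1, 1)), matrix(0, 1, 1))
  expect_equal(normalizeImage(matrix(51, 1, 1)), matrix(0.2, 1, 1))
  expect_error(normalizeImage(matrix(-1, 1, 1)), "outside")
  expect_error(normalizeImage(matrix(256, 1, 1)), "outside")
  x <- matrix(runif(20), 4, 5)
  expect_equal(normalizeImage(denormalizeImage(x)), x, tolerance = 1e-12)
})

test_that("pair resizing keeps constants, binariness, and nearest phase", {
  rp <- resizePair(matrix(0.37, 10, 10), matrix(1, 10, 10), c(256L, 256L))
  expect_identical(dim(rp$image), c(256L, 256L))
  expect_equal(rp$image, matrix(0.37, 256, 256), tolerance = 1e-9)
  expect_equal(rp$mask, matrix(1, 256, 256))
  # 4x4 checkerboard -> 8x8 with each cell duplicated into a 2x2 block
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  rp2 <- resizePair(cb, cb, c(8L, 8L))
  expect_equal(rp2$mask, cb[rep(1:4, each = 2), rep(1:4, each = 2)])
  expect_true(all(rp2$mask %in% c(0, 1)))
  expect_error(resizePair(matrix(0, 3, 3), matrix(0, 4, 4)), "differ")
})

test_that("mask merging is the pixelwise union", {
  m <- randomMask(6, 6)
  expect_equal(mergeMasks(list(m)), m)
  a <- matrix(0, 3, 3); a[1, 1] <- 1
  b <- matrix(0, 3, 3); b[3, 3] <- 1
  expect_equal(sum(mergeMasks(list(a, b))), 2)
  # overlapping counts: |A| = 5, |B| = 3, |A & B| = 2 -> union 6
  a <- matrix(0, 4, 4); a[1:5] <- 1
  b <- matrix(0, 4, 4); b[4:6] <- 1
  expect_equal(sum(a), 5); expect_equal(sum(b), 3); expect_equal(sum(a * b), 2)
  expect_equal(sum(mergeMasks(list(a, b))), 6)
  expect_error(mergeMasks(list()), "non-empty")
  expect_error(mergeMasks(list(matrix(0, 2, 2), matrix(0, 3, 3))), "shape")
})

test_that("mask merging is idempotent, commutative and associative", {
  set.seed(31)
  for (i in 1:10) {
    a <- randomMask(8, 8); b <- randomMask(8, 8); c <- randomMask(8, 8)
    expect_equal(mergeMasks(list(a, a)), a)
    expect_equal(mergeMasks(list(a, b)), mergeMasks(list(b, a)))
    expect_equal(mergeMasks(list(mergeMasks(list(a, b)), c)),
                 mergeMasks(list(a, mergeMasks(list(b, c)))))
    expect_gte(sum(mergeMasks(list(a, b, c))), max(sum(a), sum(b), sum(c)))
  }
})

test_that("stratified folds are balanced, disjoint, exhaustive, reproducible", {
  ids <- sprintf("s%02d", 1:10)
  cls <- rep(c("benign", "malignant"), 5)
  f <- makeFolds(ids, cls, k = 5, seed = 1)
  expect_equal(as.vector(table(f$fold)), rep(2L, 5))
  expect_identical(f, makeFolds(ids, cls, k = 5, seed = 1))
  expect_false(identical(f$fold, makeFolds(ids, cls, k = 5, seed = 2)$fold))
  expect_error(makeFolds(ids[1:3], cls[1:3], k = 5), "folds")
  expect_error(makeFolds(ids, cls, k = 1), "k must be")

  # benchmark-sized case: 437 benign + 210 malignant in 5 folds
  ids <- sprintf("s%03d", 1:647)
  cls <- rep(c("benign", "malignant"), c(437, 210))
  f <- makeFolds(ids, cls, k = 5, seed = 42)
  sizes <- as.vector(table(f$fold))
  expect_true(all(sizes %in% c(129L, 130L)))
  ben <- as.vector(table(f$fold[f$class == "benign"]))
  expect_true(all(ben %in% c(87L, 88L)))
  expect_true(all(as.vector(table(f$fold[f$class == "malignant"])) == 42L))
  # exhaustive and disjoint: test ids over all folds = full id list
  allTest <- unlist(lapply(1:5, function(k) foldSplit(f, k)$test))
  expect_identical(sort(allTest), sort(ids))
  sp <- foldSplit(f, 3)
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("a BUSI-style tree is indexed and preprocessed end to end", {
  d <- withr::local_tempdir()
  for (cl in c("benign", "malignant")) dir.create(file.path(d, cl))
  set.seed(7)
  writeCase <- function(cl, stem, nmask) {
    png::writePNG(matrix(runif(64), 8, 8), file.path(d, cl,
                                                     paste0(stem, ".png")))
    for (k in seq_len(nmask)) {
      sfx <- if (k == 1) "_mask" else sprintf("_mask_%d", k - 1)
      png::writePNG(randomMask(8, 8), file.path(d, cl,
                                                paste0(stem, sfx, ".png")))
    }
  }
  writeCase("benign", "b1", 1)
  writeCase("benign", "b2", 2)     # multi-mask case
  writeCase("malignant", "m1", 1)
  # an image without a mask is excluded
  png::writePNG(matrix(0.5, 8, 8), file.path(d, "benign", "nomask.png"))
  man <- indexDataset(d)
  expect_equal(nrow(man), 3)
  expect_equal(sum(man$class == "benign"), 2)
  expect_equal(lengths(strsplit(man$mask_paths, ";"))[man$id == "benign/b2"],
               2L, ignore_attr = TRUE)
  ds <- loadDataset(man, target = c(16L, 16L))
  expect_identical(dim(ds$gray), c(16L, 16L, 1L, 3L))
  expect_true(all(ds$gray >= 0 & ds$gray <= 1))
  expect_true(all(ds$mask %in% c(0, 1)))
  expect_true(all(ds$edge %in% c(0, 1)))
  expect_error(indexDataset(file.path(d, "nope")), "no such")
})
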