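test_that("cross-fusion matches the weighted-addition rule", {
  fx <- c(1, 2); fy <- c(3, 4)
  # zero weights: residual passthrough on both branches
  f0 <- fuseFeatures(fx, fy, 0, 0)
  expect_equal(f0$fx, fx)
  expect_equal(f0$fy, fy)
  # hand evaluation: fx' = fx + (1*fx + 1*fy) = (5, 8)
  f1 <- fuseFeatures(fx, fy, 1, 1)
  expect_equal(f1$fx, c(5, 8))
  expect_equal(f1$fy, c(7, 10))
  # identical branches with unit weights triple the map
  F <- matrix(runif(9), 3, 3)
  fs <- fuseFeatures(F, F, 1, 1)
  expect_equal(fs$fx, 3 * F)
  expect_equal(fs$fy, 3 * F)
  # the shared sum uses pre-update values: outputs differ only by residual
  f2 <- fuseFeatures(fx, fy, 0.5, 2)
  expect_equal(f2$fx - fx, f2$fy - fy)
  expect_error(fuseFeatures(matrix(0, 2, 2), matrix(0, 3, 3), 1, 1), "differ")
})

test_that("configuration validity is enforced", {
  expect_error(modelConfig(levels = 3, inputSize = c(30, 30)), "divisible")
  expect_error(modelConfig(dropoutRate = 1), "dropoutRate")
  expect_error(buildDBUNet(modelConfig(fusion = "none")), "dual")
  expect_error(buildGSUNet(modelConfig(fusion = "dual")), "none")
})

test_that("parameter tallies match a hand-computed layer-by-layer count", {
  cfg <- tinyModelConfig("dual")      # depth 2, base 8
  # independent oracle: sum k^2*Cin*Cout + Cout over the declared layers
  convN <- function(k, ci, co) k * k * ci * co + co
  ch <- c(8, 16); bott <- 32
  enc <- convN(3, 1, 8) + convN(3, 8, 8) + convN(3, 8, 16) + convN(3, 16, 16)
  dec <- convN(2, bott, 16) + convN(3, 32, 16) + convN(3, 16, 16) +
         convN(2, 16, 8) + convN(3, 16, 8) + convN(3, 8, 8)
  expectDual <- 2 * enc + 2 * 2 +  # two branches + (wx, wy) per level
    convN(3, 16, 32) + convN(3, 32, 32) + dec + convN(1, 8, 1)
  dbu <- buildDBUNet(cfg, seed = 1)
  expect_equal(nParameters(dbu), expectDual)
  gsu <- buildGSUNet(tinyModelConfig("none"), seed = 1)
  expect_equal(nParameters(gsu), expectDual - enc - 4)
  expect_gt(nParameters(dbu), nParameters(gsu))
  # fusion scalars: present, initialized to exactly 1, absent in GSU-Net
  fw <- fusionWeights(dbu)
  expect_equal(fw$wx, c(1, 1))
  expect_equal(fw$wy, c(1, 1))
  expect_error(fusionWeights(gsu), "single-branch")
  expect_false(any(grepl("fuse", names(gsu@params))))
})

test_that("forward pass honors shape and sigmoid-range contracts", {
  cfg <- tinyModelConfig("dual")
  m <- buildDBUNet(cfg, seed = 2)
  set.seed(1)
  g <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  e <- array(rbinom(32 * 32 * 2, 1, 0.2), c(32, 32, 1, 2))
  p <- predictProb(m, g, e)
  expect_identical(dim(p), c(32L, 32L, 1L, 2L))
  expect_true(all(is.finite(p)))
  expect_true(all(p > 0 & p < 1))
  # matrix input and auto-computed edge map
  p1 <- predictProb(m, g[, , 1, 1])
  expect_identical(dim(p1), c(32L, 32L, 1L, 1L))
  gsu <- buildGSUNet(tinyModelConfig("none"), seed = 2)
  p2 <- predictProb(gsu, g)
  expect_identical(dim(p2), c(32L, 32L, 1L, 2L))
})

test_that("with fusion weights zeroed the primary path reproduces GSU-Net", {
  dbu <- buildDBUNet(tinyModelConfig("dual"), seed = 5)
  gsu <- buildGSUNet(tinyModelConfig("none"), seed = 6)
  for (l in 1:2) {
    dbu@params[[sprintf("fuse_l%d_wx", l)]] <- 0
    dbu@params[[sprintf("fuse_l%d_wy", l)]] <- 0
  }
  # same layer names exist for the shared path; copy them across
  shared <- names(gsu@params)
  expect_true(all(shared %in% names(dbu@params)))
  for (nm in shared) gsu@params[[nm]] <- dbu@params[[nm]]
  set.seed(3)
  g <- array(runif(32 * 32), c(32, 32, 1, 1))
  e <- array(rbinom(32 * 32, 1, 0.3), c(32, 32, 1, 1))
  expect_equal(predictProb(dbu, g, e), predictProb(gsu, g),
               tolerance = 1e-12)
})

test_that("initialization and forward are deterministic in the seed", {
  m1 <- buildDBUNet(tinyModelConfig("dual"), seed = 9)
  m2 <- buildDBUNet(tinyModelConfig("dual"), seed = 9)
  expect_identical(m1@params, m2@params)
  m3 <- buildDBUNet(tinyModelConfig("dual"), seed = 10)
  expect_false(identical(m1@params, m3@params))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- modelConfig(levels = 2L, baseChannels = 2L, dropoutRate = 0,
                     inputSize = c(8L, 8L), fusion = "dual")
  m <- buildDBUNet(cfg, seed = 3)
  set.seed(1)
  # nudge parameters off the ReLU kinks that zero-init biases sit on
  for (nm in names(m@params))
    m@params[[nm]] <- m@params[[nm]] +
      runif(length(m@params[[nm]]), -0.05, 0.05)
  g <- array(runif(64 * 2), c(8, 8, 1, 2))
  e <- array(rbinom(64 * 2, 1, 0.3) + runif(64 * 2, 0, 1e-3), c(8, 8, 1, 2))
  t <- array(rbinom(64 * 2, 1, 0.4), c(8, 8, 1, 2))
  res <- modelGradients(m, g, t, e, train = FALSE)
  lossAt <- function(mm) modelGradients(mm, g, t, e, train = FALSE)$loss
  eps <- 1e-6
  for (nm in c("enc_x_l1_c1_W", "enc_y_l2_c2_W", "fuse_l1_wx", "fuse_l2_wy",
               "bot_c1_W", "dec_l1_c2_W", "dec_l2_up_W", "out_W", "out_b")) {
    p <- m@params[[nm]]
    for (j in sample(seq_along(p), min(2, length(p)))) {
      mp <- m; mp@params[[nm]][j] <- p[j] + eps
      mm <- m; mm@params[[nm]][j] <- p[j] - eps
      num <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
      expect_equal(res$grads[[nm]][j], num, tolerance = 1e-3)
    }
  }
})

test_that("training steps are deterministic and reduce the loss", {
  pcfg <- tinyPhantomConfig(seed = 21, size = 32L)
  ds <- phantomDataset(4, pcfg)
  cfg <- modelConfig(levels = 2L, baseChannels = 4L, inputSize = c(32L, 32L),
                     fusion = "dual")
  m <- buildDBUNet(cfg, seed = 1)
  f1 <- fitSteps(m, ds$gray, ds$mask, ds$edge, steps = 5L, batchSize = 4L,
                 lr = 1e-3, seed = 7)
  f2 <- fitSteps(m, ds$gray, ds$mask, ds$edge, steps = 5L, batchSize = 4L,
                 lr = 1e-3, seed = 7)
  expect_identical(f1$lossHistory, f2$lossHistory)
  expect_identical(f1$model@params, f2$model@params)
  f3 <- fitSteps(m, ds$gray, ds$mask, ds$edge, steps = 50L, batchSize = 4L,
                 lr = 1e-3, seed = 7)
  expect_lt(f3$lossHistory[50], f3$lossHistory[1])
})
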