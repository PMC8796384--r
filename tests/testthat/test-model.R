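test_that("CyclicConv wraps the receptive field around the span", {
  # sequence A,B,C with k = 3: fields are (C,A,B), (A,B,C), (B,C,A)
  m <- buildFeatureMap(matrix(c(1, 2, 3), 1), "p")
  kern <- matrix(c(0.5, -1, 2), 1)
  out <- mapValues(cyclicConv1d(m, kern))
  span <- (m@start + 1):(m@start + 3)
  expect_equal(out[1, span],
               c(sum(kern * c(3, 1, 2)),
                 sum(kern * c(1, 2, 3)),
                 sum(kern * c(2, 3, 1))))
  # k = 1 identity kernel reproduces the input
  expect_equal(mapValues(cyclicConv1d(m, matrix(1, 1, 1))), mapValues(m))
  expect_error(cyclicConv1d(m, matrix(1, 1, 5)), "kernel larger than ring")
  expect_error(cyclicConv1d(m, matrix(1, 1, 2)), "odd")
})

test_that("CyclicConv equals ordinary valid convolution on a wrap-padded span", {
  oracle <- function(block, kern) {
    n <- ncol(block); k <- ncol(kern); pad <- (k - 1) / 2
    padded <- cbind(block[, (n - pad + 1):n, drop = FALSE], block,
                    block[, 1:pad, drop = FALSE])
    out <- matrix(0, nrow(block), n)
    for (j in 1:n) for (t in 1:k)
      out[, j] <- out[, j] + kern[, t] * padded[, j + t - 1]
    out
  }
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(3:15, 1)
    k <- sample(c(3L, 5L), 1)
    if (k > n) k <- 3L
    D <- sample(1:4, 1)
    block <- matrix(rnorm(D * n), D, n)
    kern <- matrix(rnorm(D * k), D, k)
    m <- buildFeatureMap(block, "p")
    got <- mapValues(cyclicConv1d(m, kern))[, (m@start + 1):(m@start + n),
                                            drop = FALSE]
    expect_lt(max(abs(got - oracle(block, kern))), 1e-6)
  }
})

test_that("variants fix the convolution kind and augmentation flag", {
  cfg <- ppbModelConfig(variant = "baseline")
  expect_equal(cfg$convKind, "ordinary"); expect_false(cfg$augment)
  cfg <- ppbModelConfig(variant = "cyclicconv")
  expect_equal(cfg$convKind, "cyclic"); expect_false(cfg$augment)
  cfg <- ppbModelConfig(variant = "augmented")
  expect_equal(cfg$convKind, "ordinary"); expect_true(cfg$augment)
  cfg <- ppbModelConfig(variant = "cyclicconv_augmented")
  expect_equal(cfg$convKind, "cyclic"); expect_true(cfg$augment)
})

test_that("invalid configurations fail at build time", {
  expect_error(ppbModelConfig(convLayers = list(list(kernel = 4, channels = 8))),
               "odd")
  expect_error(ppbModelConfig(pooling = "flatten"), "empty conv stack")
  expect_error(ppbModelConfig(D = 0), "D must be")
  expect_error(ppbModelConfig(fcLayers = c(8, 0)), "fc widths")
})

test_that("two builds with the same seed share identical initial parameters", {
  cfg <- smallConfig()
  expect_identical(buildPPBModel(cfg)@params, buildPPBModel(cfg)@params)
  cfg2 <- smallConfig(seed = 2L)
  expect_false(identical(buildPPBModel(cfg)@params$conv[[1]]$W,
                         buildPPBModel(cfg2)@params$conv[[1]]$W))
})

test_that("a small capacity model overfits ten peptides to MAE below 1", {
  ts <- tinyTrainSet()
  cfg <- smallConfig(epochs = 400L, batchSize = 10L)
  mod <- trainPPBModel(ts$maps, ts$labels, cfg)
  pr <- predictPPB(mod, ts$maps, augment = FALSE)
  expect_lt(mean(abs(pr$y_hat_raw - ts$labels)), 1)
})

test_that("zero learning rate leaves trainable parameters and loss unchanged", {
  ts <- tinyTrainSet()
  cfg <- smallConfig(epochs = 5L, lr = 0)
  mod <- trainPPBModel(ts$maps, ts$labels, cfg)
  init <- buildPPBModel(cfg)@params
  expect_equal(mod@params$conv[[1]]$W, init$conv[[1]]$W)
  expect_equal(mod@params$fc[[1]]$W, init$fc[[1]]$W)
  h <- trainingHistory(mod)
  expect_equal(diff(range(h$train_loss)), 0, tolerance = 1e-9)
})

test_that("training is reproducible under a fixed seed", {
  ts <- tinyTrainSet()
  cfg <- smallConfig(epochs = 12L)
  m1 <- trainPPBModel(ts$maps, ts$labels, cfg)
  m2 <- trainPPBModel(ts$maps, ts$labels, cfg)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(m1@params, m2@params)
})

test_that("labels outside the clamped range are rejected", {
  ts <- tinyTrainSet(npep = 4)
  bad <- ts$labels; bad[1] <- 42
  expect_error(trainPPBModel(ts$maps, bad, smallConfig(epochs = 2L)),
               "clamped")
})

test_that("predictions are clamped to [50, 95] after replica averaging", {
  mod <- buildPPBModel(smallConfig())
  m <- randomMap(6, seed = 9)
  # untrained net with identity label scale predicts near 0 -> floor clamp
  pr <- predictPPB(mod, m, augment = FALSE)
  expect_equal(pr$y_hat, 50)
  # shift the output scale so the raw mean exceeds the ceiling
  mod@params$labelNorm <- list(mu = 101.3, sd = 1)
  pr2 <- predictPPB(mod, m, augment = TRUE)
  expect_gt(pr2$y_hat_raw, 95)
  expect_equal(pr2$y_hat, 95)
  expect_equal(pr2$n_replicas, 6L * 10L)
})

test_that("augmented prediction is invariant to the presented ring rotation", {
  ts <- tinyTrainSet(npep = 6, n = 6)
  mod <- trainPPBModel(ts$maps, ts$labels, smallConfig(variant = "cyclicconv_augmented",
                                                       epochs = 15L))
  block <- MacrocyclePPB:::.spanBlock(ts$maps[[1]])
  for (r in 1:5) {
    rot <- buildFeatureMap(block[, c((r + 1):6, 1:r)], "p1")
    expect_equal(predictPPB(mod, rot)$y_hat_raw,
                 predictPPB(mod, ts$maps[[1]])$y_hat_raw, tolerance = 1e-12)
  }
})

test_that("prediction rejects maps of the wrong shape", {
  mod <- buildPPBModel(smallConfig())
  bad <- buildFeatureMap(matrix(1, 2, 5), "p")  # D = 2, model expects 3
  expect_error(predictPPB(mod, bad), "shape mismatch")
})
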