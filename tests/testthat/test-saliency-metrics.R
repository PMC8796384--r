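test_that("saliency of a purely linear network equals |weights|", {
  cfg <- ppbModelConfig(variant = "baseline", D = 3, convLayers = list(),
                        pooling = "flatten", fcLayers = integer(0),
                        batchNorm = FALSE, activation = "identity", seed = 4)
  mod <- buildPPBModel(cfg)
  W <- mod@params$fc[[1]]$W
  m <- randomMap(7, seed = 2)
  expect_equal(saliencyMatrix(mod, m), abs(matrix(W, 3, 15)),
               ignore_attr = TRUE)
  # constant model: zero weights give zero saliency everywhere
  mod@params$fc[[1]]$W[] <- 0
  expect_true(all(saliencyMatrix(mod, m) == 0))
})

test_that("saliency matches central finite differences on a trained network", {
  ts <- tinyTrainSet()
  mod <- trainPPBModel(ts$maps, ts$labels, smallConfig(epochs = 60L))
  for (i in c(1, 4)) {
    m <- ts$maps[[i]]
    sa <- saliencyMatrix(mod, m)
    fd <- MacrocyclePPB:::.saliencyFiniteDiff(mod, m, h = 1e-3)
    span <- (m@start + 1):(m@start + m@n)
    rel <- abs(sa[, span] - fd[, span]) / pmax(abs(fd[, span]), 1e-6)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("aggregated saliency reduces to the span slice for a single replica", {
  ts <- tinyTrainSet(npep = 4)
  mod <- trainPPBModel(ts$maps, ts$labels, smallConfig(epochs = 10L))
  m <- ts$maps[[2]]
  agg <- aggregateSaliency(mod, m, augment = FALSE)
  raw <- saliencyMatrix(mod, m)[, (m@start + 1):(m@start + m@n)]
  expect_equal(saliencyScores(agg), raw, ignore_attr = TRUE)
  expect_equal(substructureSaliency(agg), unname(colSums(raw)))
})

test_that("pure translation replicas produce identical saliency", {
  ts <- tinyTrainSet(npep = 4, n = 6)
  mod <- trainPPBModel(ts$maps, ts$labels, smallConfig(epochs = 10L))
  block <- MacrocyclePPB:::.spanBlock(ts$maps[[1]])
  reps <- augmentFeatureMap(ts$maps[[1]])
  same <- Filter(function(r) r@rotation == 0L, reps)
  sal <- lapply(same[1:3], function(r) {
    s <- saliencyMatrix(mod, r)
    s[, (r@start + 1):(r@start + r@n)]
  })
  expect_lt(max(abs(sal[[1]] - sal[[2]])), 1e-6)
  expect_lt(max(abs(sal[[1]] - sal[[3]])), 1e-6)
})

test_that("aggregated saliency is invariant to the decomposition anchor", {
  ts <- tinyTrainSet(npep = 4, n = 6)
  mod <- trainPPBModel(ts$maps, ts$labels, smallConfig(epochs = 10L))
  m <- ts$maps[[1]]
  block <- MacrocyclePPB:::.spanBlock(m)
  rot <- buildFeatureMap(block[, c(3:6, 1:2)], "p1")  # re-anchored by 2
  a1 <- saliencyScores(aggregateSaliency(mod, m))
  a2 <- saliencyScores(aggregateSaliency(mod, rot))
  # same values, relabeled ring positions
  expect_equal(a2, a1[, c(3:6, 1:2)], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("saliency ranking recovers a planted important position", {
  for (seed in 1:3) {
    set.seed(200 + seed)
    maps <- list(); labels <- numeric(0)
    for (i in 1:40) {
      block <- matrix(rnorm(2 * 6, 0, 0.3), 2, 6)
      block[1, 1] <- rnorm(1, 3, 0.5)       # position 0 carries the signal
      maps[[i]] <- buildFeatureMap(block, paste0("p", i))
      labels[i] <- pmin(95, pmax(50, 50 + 12 * block[1, 1] + rnorm(1, 0, 1)))
    }
    cfg <- ppbModelConfig(variant = "augmented", D = 2,
                          convLayers = list(list(kernel = 3, channels = 8)),
                          fcLayers = c(8), epochs = 60, patience = Inf,
                          batchSize = 32, valFraction = 0, lr = 3e-3,
                          seed = seed)
    mod <- trainPPBModel(maps, labels, cfg)
    tops <- vapply(maps[1:15], function(m)
      which.max(substructureSaliency(aggregateSaliency(mod, m))), integer(1))
    expect_gt(mean(tops == 1L), 0.5, label = paste("seed", seed))
  }
})

test_that("MAE and R match the worked example and a brute-force oracle", {
  expect_equal(evaluatePPB(c(62, 66), c(60, 70))$mae, 3)
  ex <- evaluatePPB(c(60, 70, 80), c(60, 70, 80))
  expect_equal(ex$mae, 0); expect_equal(ex$r, 1)
  set.seed(12)
  for (rep in 1:5) {
    y <- runif(50, 50, 95)
    yhat <- runif(50, 40, 100)
    got <- evaluatePPB(y, yhat, "50-95")
    yc <- pmin(95, pmax(50, yhat))
    mae <- sum(abs(y - yc)) / 50
    r <- sum((yc - mean(yc)) * (y - mean(y))) /
      sqrt(sum((yc - mean(yc))^2) * sum((y - mean(y))^2))
    expect_equal(got$mae, mae, tolerance = 1e-12)
    expect_equal(got$r, r, tolerance = 1e-12)
  }
})

test_that("the 80-95 range filters on experimental values and applies the ceiling", {
  y    <- c(85, 90, 75, 82)
  yhat <- c(97, 70, 90, 84)   # record 3: high prediction, low experiment
  got <- evaluatePPB(y, yhat, "80-95")
  expect_equal(got$n_evaluated, 3L)           # record 3 excluded
  expect_equal(got$mae, mean(abs(c(85, 90, 82) - c(95, 70, 84))))
  # predictions below 50 are NOT floored in the 80-95 range
  got2 <- evaluatePPB(c(85, 90), c(40, 90), "80-95")
  expect_equal(got2$mae, mean(abs(c(85, 90) - c(40, 90))))
})

test_that("metric symmetries hold and degenerate inputs are flagged", {
  y <- c(60, 70, 85); yhat <- c(65, 72, 80)
  expect_equal(evaluatePPB(y, yhat)$mae, evaluatePPB(yhat, y)$mae)
  # R is invariant to positive affine rescaling of predictions
  expect_equal(evaluatePPB(y, yhat)$r,
               evaluatePPB(y, yhat * 0.5 + 35)$r, tolerance = 1e-12)
  one <- evaluatePPB(c(85), c(90), "80-95")
  expect_false(one$r_defined)
  expect_true(is.na(one$r))
})
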