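test_that("valid-convolution output sizes follow floor((in - k)/stride) + 1", {
  expect_equal(convOutputSize(26, 7, 2), 10)
  expect_equal(convOutputSize(26, 3, 1), 24)
  expect_equal(convOutputSize(10, 10, 1), 1)
  expect_error(convOutputSize(5, 7, 1), "exceeds")
  expect_error(convOutputSize(5, 3, 0), "stride")
})

test_that("architecture builders encode the published layer settings", {
  reg <- buildRegressorSpec(c(26, 26))
  stack <- reg$convStacks[[1]]
  expect_length(stack, 2)
  expect_equal(stack[[1]]$nKernels, 64)
  expect_equal(stack[[1]]$kernel, c(7, 7))
  expect_equal(stack[[1]]$stride, 2)
  expect_equal(stack[[1]]$padding, "valid")
  expect_equal(reg$denseSizes, c(256L, 64L))
  expect_equal(reg$dropoutKeep, 0.7)
  expect_equal(reg$head, "regression")
  # 26 -> 10 -> 2 through the two stride-2 7x7 convs
  expect_equal(reg$flatLengths, 2 * 2 * 64)

  cls <- buildClassifierSpec(c(26, 26))
  expect_equal(sapply(cls$convStacks[[1]], `[[`, "nKernels"), c(16, 32, 64))
  expect_equal(cls$convStacks[[1]][[3]]$kernel, c(3, 3))
  expect_equal(cls$denseSizes, c(256L, 64L))
  expect_equal(cls$head, "binary_classification")

  hyb <- buildHybridSpec(c(35, 35), c(32, 32))
  expect_length(hyb$inputShapes, 2)
  expect_equal(hyb$denseSizes, c(305L, 175L))
  armStride <- function(i) hyb$convStacks[[i]][[3]]$stride
  expect_equal(armStride(1), 2)  # cell arm
  expect_equal(armStride(2), 1)  # drug arm
  expect_equal(sapply(hyb$convStacks[[1]], function(s) s$nKernels),
               c(60, 72, 72))

  # shape underflow is rejected naming the layer
  expect_error(buildRegressorSpec(c(10, 10)), "conv layer 2")
})

test_that("the first regressor conv layer has 3200 trainable parameters", {
  spec <- buildRegressorSpec(c(26, 26))
  set.seed(1)
  net <- refinedmap:::buildNetwork(spec)
  counts <- modelParameterCounts(list(arms = net$arms, joint = net$joint))
  conv1 <- counts[counts$segment == "arm1" & counts$type == "conv", ][1, ]
  expect_equal(conv1$nParams, 64 * (7 * 7 * 1 + 1))  # 3200

  # spec-to-network translation preserves structure
  types <- sapply(net$arms[[1]], `[[`, "type")
  expect_equal(types, rep(c("conv", "bn", "relu", "regroup"), 2))
  expect_equal(dim(net$arms[[1]][[1]]$W), c(49, 64))
  expect_equal(net$arms[[1]][[5]]$stride, 2)
  jointTypes <- sapply(net$joint, `[[`, "type")
  expect_equal(jointTypes, c("dense", "bn", "relu", "dense", "bn", "relu",
                             "dropout", "dense"))
  expect_equal(dim(net$joint[[1]]$W), c(256, 256))  # 2*2*64 inputs
  expect_equal(dim(net$joint[[4]]$W), c(256, 64))
})

test_that("analytic gradients match numerical differentiation", {
  spec <- buildRegressorSpec(c(6, 6), nKernels = 3, kernel = c(3, 3),
                             stride = 1, nConv = 2, denseSizes = c(5, 4),
                             dropoutKeep = 1)
  set.seed(3)
  net <- refinedmap:::buildNetwork(spec)
  n <- 4
  x <- matrix(runif(n * 36), n, 36)
  y <- runif(n)
  lossAt <- function(net) {
    fw <- refinedmap:::modelForward(net, list(x), train = TRUE)
    mean((fw$out[, 1] - y)^2)
  }
  fw <- refinedmap:::modelForward(net, list(x), train = TRUE)
  dz <- matrix(2 * (fw$out[, 1] - y) / n, ncol = 1)
  jb <- refinedmap:::segmentBackward(net$joint, fw$jointCache, dz)
  ab <- refinedmap:::segmentBackward(net$arms[[1]], fw$armCaches[[1]], jb$dx)
  eps <- 1e-6
  setParam <- function(net, seg, i, nm, k, v) {
    if (seg == "joint") net$joint[[i]][[nm]][k] <- v
    else net$arms[[1]][[i]][[nm]][k] <- v
    net
  }
  getParam <- function(net, seg, i, nm, k) {
    if (seg == "joint") net$joint[[i]][[nm]][k]
    else net$arms[[1]][[i]][[nm]][k]
  }
  checkSeg <- function(seg, grads) {
    for (i in seq_along(grads)) {
      g <- grads[[i]]
      if (is.null(g)) next
      for (nm in names(g)) {
        for (k in unique(round(seq(1, length(g[[nm]]), length.out = 3)))) {
          orig <- getParam(net, seg, i, nm, k)
          up <- lossAt(setParam(net, seg, i, nm, k, orig + eps))
          dn <- lossAt(setParam(net, seg, i, nm, k, orig - eps))
          expect_equal(g[[nm]][k], (up - dn) / (2 * eps), tolerance = 1e-4)
        }
      }
    }
  }
  checkSeg("joint", jb$grads)
  checkSeg("arms", ab$grads)
})

test_that("training bookkeeping: history, finiteness, descent, determinism", {
  set.seed(22)
  ds <- simulateDataset(120, 16, gamma = 0.6, spuriousFrac = 0.25, seed = 6)
  m <- randomMap(featureNames(ds@table), seed = 1)
  imgs <- vectorsToImages(ds@table, m)
  split <- trainValTestSplit(120, seed = 2)
  spec <- buildRegressorSpec(c(4, 4), nKernels = 8, kernel = c(2, 2),
                             stride = 1, denseSizes = c(16, 8))

  one <- trainModel(spec, imgs, ds@y, split,
                    trainConfig(epochs = 1, batchSize = 32, seed = 5))
  expect_equal(nrow(one$history), 1)
  expect_true(all(is.finite(one$history$trainLoss)))

  cfg <- trainConfig(lr = 3e-3, epochs = 150, batchSize = 32, seed = 5,
                     earlyStopPatience = 150)
  mod <- trainModel(spec, imgs, ds@y, split, cfg)
  expect_true(all(is.finite(mod$history$trainLoss)))
  # training reduced the training loss relative to the first epoch
  expect_lt(min(mod$history$trainLoss), mod$history$trainLoss[1])
  # fit beats the mean predictor in-sample after training
  predTrain <- predictModel(mod, imgs)[split$train]
  expect_lt(nrmse(ds@y[split$train], predTrain), 1)

  # identical seed, identical weights and history
  mod2 <- trainModel(spec, imgs, ds@y, split, cfg)
  expect_identical(mod2$history, mod$history)
  expect_identical(predictModel(mod2, imgs), predictModel(mod, imgs))

  # predictions are independent of prediction batch size (eval mode)
  p1 <- predictModel(mod, imgs, batchSize = 1)
  p64 <- predictModel(mod, imgs, batchSize = 64)
  expect_equal(p1, p64, tolerance = 1e-9)
})

test_that("classifier heads emit probabilities and train on labels", {
  set.seed(31)
  ds <- simulateDataset(150, 16, gamma = 0.5, spuriousFrac = 0, seed = 9)
  labels <- as.integer(ds@y > median(ds@y))
  m <- randomMap(featureNames(ds@table), seed = 3)
  imgs <- vectorsToImages(ds@table, m)
  split <- trainValTestSplit(150, seed = 4)
  spec <- architectureSpec(list(c(4, 4)),
                           list(list(convLayerSpec(8, c(2, 2), 1))),
                           denseSizes = c(16, 8), dropoutKeep = 0.7,
                           head = "binary_classification")
  mod <- trainModel(spec, imgs, labels, split,
                    trainConfig(lr = 3e-3, epochs = 10, batchSize = 32,
                                seed = 2))
  pr <- predictModel(mod, imgs)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_gt(auroc(labels[split$train], pr[split$train]), 0.5)
})

test_that("the two-arm hybrid consumes paired image sets", {
  set.seed(41)
  ds <- simulateDataset(90, 9, gamma = 0.5, spuriousFrac = 0, seed = 11)
  ds2 <- simulateDataset(90, 16, gamma = 0.5, spuriousFrac = 0, seed = 12)
  imgsA <- vectorsToImages(ds@table, randomMap(featureNames(ds@table), 1))
  imgsB <- vectorsToImages(ds2@table, randomMap(featureNames(ds2@table), 2))
  split <- trainValTestSplit(90, seed = 1)
  spec <- architectureSpec(
    list(c(3, 3), c(4, 4)),
    list(list(convLayerSpec(4, c(2, 2), 1)),
         list(convLayerSpec(4, c(2, 2), 1))),
    denseSizes = c(8, 4), dropoutKeep = 0.7, head = "regression")
  mod <- trainModel(spec, list(imgsA, imgsB), ds@y, split,
                    trainConfig(epochs = 3, batchSize = 32, seed = 3))
  expect_equal(nrow(mod$history), 3)
  expect_length(predictModel(mod, list(imgsA, imgsB)), 90)

  # a missing arm is rejected up front
  expect_error(trainModel(spec, imgsA, ds@y, split,
                          trainConfig(epochs = 1)), "2 input")
})

test_that("dense reference networks run on flat feature vectors", {
  set.seed(51)
  ds <- simulateDataset(100, 12, seed = 13)
  split <- trainValTestSplit(100, seed = 5)
  spec <- buildDenseSpec(12, hidden = c(16, 8))
  mod <- trainModel(spec, values(ds@table), ds@y, split,
                    trainConfig(lr = 3e-3, epochs = 120, batchSize = 32,
                                seed = 7, earlyStopPatience = 120))
  pred <- predictModel(mod, values(ds@table))
  expect_lt(nrmse(ds@y[split$train], pred[split$train]), 1)
})
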