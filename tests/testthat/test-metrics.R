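test_that("regression metrics match hand-computed oracles", {
  y <- c(0, 1, 2); yhat <- c(0, 1, 1)
  expect_equal(nrmse(y, yhat), 1 / sqrt(2), tolerance = 1e-10)
  # MAE ratio: (1/3) / (2/3)
  expect_equal(nmae(y, yhat), 0.5, tolerance = 1e-10)
  expect_equal(pcc(1:4, c(1, 3, 2, 4)), 0.8, tolerance = 1e-10)

  # definitional anchors
  y2 <- c(0.2, 0.5, 0.9, 0.4)
  expect_equal(nrmse(y2, rep(mean(y2), 4)), 1)
  expect_equal(nrmse(y2, y2), 0)
  expect_equal(nmae(y2, rep(mean(y2), 4)), 1)
  expect_equal(pcc(y2, 2 * y2 + 3), 1)
  expect_equal(pcc(y2, -y2), -1)

  expect_error(nrmse(rep(1, 3), c(1, 2, 3)), "constant")
  expect_error(pcc(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(nrmse(1:3, 1:4), "lengths differ")
})

test_that("metric identities hold on random draws (property check)", {
  set.seed(33)
  for (i in 1:100) {
    y <- rnorm(20)
    expect_equal(nrmse(y, rep(mean(y), 20)), 1, tolerance = 1e-12)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pcc(y, a * y + b), 1, tolerance = 1e-9)
    expect_equal(pcc(y, -a * y + b), -1, tolerance = 1e-9)
  }
})

test_that("bias angle follows both stated conventions", {
  set.seed(2)
  y <- runif(30, 0.1, 1)

  # residuals proportional to y: zero angle between y and eps
  ba <- biasAngle(y, y - 0.5 * y)
  expect_equal(ba$thetaDegrees, 0, tolerance = 1e-6)
  expect_equal(ba$bias, 0, tolerance = 1e-6)

  # orthogonal residuals: 90 degrees
  eps <- rnorm(30)
  eps <- eps - y * sum(eps * y) / sum(y^2)
  ba90 <- biasAngle(y, y - eps)
  expect_equal(ba90$thetaDegrees, 90, tolerance = 1e-6)

  # OLS convention: eps = 0.5 (y - mean(y)) gives slope 0.5
  yhat <- y - 0.5 * (y - mean(y))
  baOls <- biasAngle(y, yhat, mode = "ols_slope")
  expect_equal(baOls$bias, 0.5, tolerance = 1e-9)
  expect_equal(baOls$thetaDegrees, atan(0.5) * 180 / pi, tolerance = 1e-9)

  # perfect prediction is flagged, not fatal
  expect_warning(out <- biasAngle(y, y), "perfect")
  expect_equal(out$bias, 0)
})

test_that("classification metrics match their defining ratios", {
  perfect <- classificationMetrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, fpr = 0))

  sym <- classificationMetrics(c(TP = 1, TN = 1, FP = 1, FN = 1))
  expect_equal(unlist(sym)[c("accuracy", "precision", "recall", "f1")],
               c(accuracy = .5, precision = .5, recall = .5, f1 = .5))

  m <- classificationMetrics(c(TP = 8, TN = 6, FP = 2, FN = 4))
  expect_equal(m$precision, 0.8, tolerance = 1e-10)
  expect_equal(m$recall, 2 / 3, tolerance = 1e-10)
  expect_equal(m$f1, 8 / 11, tolerance = 1e-10)
  expect_equal(m$accuracy, 0.7, tolerance = 1e-10)
  expect_equal(m$fpr, 0.25, tolerance = 1e-10)

  # zero denominator flags the field instead of failing
  noPos <- classificationMetrics(c(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(noPos$precision))
  expect_equal(noPos$accuracy, 1)

  cc <- confusionCounts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(cc, c(TP = 2, TN = 1, FP = 1, FN = 1))
})

test_that("AUROC equals the rank statistic with tie handling", {
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(auroc(c(1, 1, 1), c(0.1, 0.5, 0.9)), "both classes")
})

test_that("gap statistics separate a perfect model from a null and detect parity", {
  set.seed(10)
  yTrain <- runif(200)
  yTest <- runif(60)

  # a perfect model: its NRMSE centroid sits near 0, the null's near 1+
  gsPerf <- gapStatistics(yTest, yTest, yTrain, metrics = c("nrmse", "pcc"),
                          reps = 600, seed = 3)
  expect_lt(gsPerf$nrmse$centroids[1], 0.1)
  expect_gt(gsPerf$nrmse$centroids[2], 0.9)
  expect_gt(gsPerf$nrmse$gap, 0.8)

  # a model that IS the null generator: the pooled distributions coincide,
  # so the k-means split leaves only the within-distribution spread — an
  # order of magnitude below the perfect-model gap
  nullLike <- sample(yTrain, 60, replace = TRUE)
  gsNull <- gapStatistics(yTest, nullLike, yTrain, metrics = "nrmse",
                          reps = 600, seed = 2)
  expect_lt(abs(gsNull$nrmse$gap), 0.25 * gsPerf$nrmse$gap)

  # exact reproducibility under the seed
  gsPerf2 <- gapStatistics(yTest, yTest, yTrain, metrics = c("nrmse", "pcc"),
                           reps = 600, seed = 3)
  expect_identical(gsPerf$nrmse$model, gsPerf2$nrmse$model)
  expect_error(gapStatistics(yTest, yTest, yTrain, reps = 1), "replicates")
})

test_that("robustness counts strict bootstrap wins", {
  set.seed(4)
  y <- runif(50)
  # ties never count as wins
  expect_equal(robustness(y, y + 0.1, y + 0.1, reps = 200, seed = 1), 0)
  # a perfect model dominates a shuffled one
  frac <- robustness(y, y, sample(y), reps = 400, seed = 2)
  expect_gt(frac, 0.99)
  # orientation flips for correlation
  fracP <- robustness(y, y, sample(y), metric = "pcc", reps = 400, seed = 2)
  expect_gt(fracP, 0.99)
  expect_identical(robustness(y, y, sample(y), reps = 100, seed = 9),
                   robustness(y, y, sample(y), reps = 100, seed = 9))
})

test_that("bootstrap confidence intervals behave at the boundaries", {
  set.seed(5)
  y <- runif(40)
  ci0 <- jabCI(y, y, metric = "nrmse", reps = 200, seed = 1)
  expect_equal(ci0, c(0, 0))
  yhat <- y + rnorm(40, sd = 0.1)
  ci <- jabCI(y, yhat, metric = "nrmse", reps = 400, seed = 2)
  expect_lte(ci[1], ci[2])
  # point estimate falls inside its own bootstrap interval here
  pt <- nrmse(y, yhat)
  expect_true(pt >= ci[1] && pt <= ci[2])
})

test_that("binomial proportion intervals match the closed forms", {
  ci <- binomialCI(50, 100)
  z <- qnorm(0.975)
  expect_equal(ci, c(0.5 - z * 0.05, 0.5 + z * 0.05), tolerance = 1e-10)
  expect_equal(binomialCI(10, 10)[2], 1)   # clipped at 1
  expect_equal(binomialCI(0, 10)[1], 0)
  ciW <- binomialCI(50, 100, method = "wilson")
  expect_lt(ciW[2] - ciW[1], ci[2] - ci[1] + 1e-9)
  expect_error(binomialCI(5, 0), "positive")
})

test_that("McNemar test uses the exact branch for few discordant pairs", {
  # b = 10, c = 0: exact two-sided binomial p = 2 * 0.5^10
  a <- c(rep(TRUE, 10), rep(TRUE, 5))
  b <- c(rep(FALSE, 10), rep(TRUE, 5))
  out <- mcnemarTest(a, b)
  expect_equal(out$method, "exact")
  expect_equal(out$pValue, 2 * 0.5^10, tolerance = 1e-12)

  # b = c symmetric disagreement: p = 1 under the exact test
  a2 <- c(rep(TRUE, 4), rep(FALSE, 4))
  b2 <- c(rep(FALSE, 4), rep(TRUE, 4))
  expect_equal(mcnemarTest(a2, b2)$pValue, 1)

  # identical correctness vectors are flagged
  expect_warning(outSame <- mcnemarTest(a, a), "no discordant")
  expect_equal(outSame$pValue, 1)

  # large discordant counts switch to chi-square with continuity correction
  a3 <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 20))
  b3 <- c(rep(FALSE, 30), rep(TRUE, 10), rep(TRUE, 20))
  out3 <- mcnemarTest(a3, b3)
  expect_equal(out3$method, "chi-square")
  expect_equal(out3$statistic, (abs(30 - 10) - 1)^2 / 40, tolerance = 1e-10)
})

test_that("residual-regression bias correction removes linear bias", {
  set.seed(7)
  y <- runif(80, 0.1, 0.9)

  # unbiased predictions are (numerically) unchanged
  pred <- y
  corrected <- bc1Correct(y, pred, regressor = "observed", newY = y)
  expect_equal(corrected, pred, tolerance = 1e-9)

  # residuals exactly linear in y: observed-regressor correction zeroes the
  # post-correction residual slope on the fitting set
  biased <- 0.2 + 0.6 * y        # eps = y - biased = -0.2 + 0.4 y
  corr <- bc1Correct(y, biased, regressor = "observed", newY = y)
  slope <- coef(lm((y - corr) ~ y))[2]
  expect_equal(unname(slope), 0, tolerance = 1e-10)
  # and here the correction is exact
  expect_equal(corr, y, tolerance = 1e-9)

  # prediction-regressor mode (test time): the held-out residual trend
  # (slope convention) shrinks towards zero
  yNew <- runif(200, 0.1, 0.9)
  biasedNew <- 0.2 + 0.6 * yNew + rnorm(200, sd = 0.01)
  fitPred <- 0.2 + 0.6 * y + rnorm(80, sd = 0.01)
  correctedNew <- bc1Correct(y, fitPred, newPred = biasedNew)
  before <- biasAngle(yNew, biasedNew, mode = "ols_slope")$bias
  after <- biasAngle(yNew, correctedNew, mode = "ols_slope")$bias
  expect_lt(abs(after), abs(before))
  # and the corrected predictions are close to the truth
  expect_lt(nrmse(yNew, correctedNew), 0.2)

  expect_error(bc1Correct(rep(1, 5), runif(5)), "constant")
})

test_that("stacking weights live on the simplex and dominate single models", {
  set.seed(9)
  yVal <- runif(50)

  # single model: identity with weight 1
  one <- stackPredictions(yVal, cbind(yVal + 0.1))
  expect_equal(one$weights, 1)
  expect_equal(one$stacked, yVal + 0.1)

  # an exact-fit model takes all the weight
  preds <- cbind(m1 = yVal + rnorm(50, sd = 0.2), m2 = yVal,
                 m3 = rev(yVal))
  ex <- stackPredictions(yVal, preds)
  expect_equal(ex$weights, c(0, 1, 0))

  # stacked validation error never exceeds the best single model
  for (i in 1:5) {
    v <- sapply(1:4, function(j) yVal + rnorm(50, sd = runif(1, 0.05, 0.4)))
    st <- stackPredictions(yVal, v)
    expect_true(all(st$weights >= -1e-12))
    expect_equal(sum(st$weights), 1, tolerance = 1e-9)
    stackedNrmse <- nrmse(yVal, st$stacked)
    singles <- apply(v, 2, function(p) nrmse(yVal, p))
    expect_lte(stackedNrmse, min(singles) + 1e-9)
  }

  expect_error(stackPredictions(yVal, matrix(nrow = 50, ncol = 0)),
               "at least one")
})

test_that("evaluation reports collect the standard fields", {
  set.seed(13)
  y <- runif(40)
  yhat <- y + rnorm(40, sd = 0.1)
  rep1 <- evaluationReport(y, yhat)
  expect_named(rep1, c("nrmse", "pcc", "bias", "theta_degrees",
                       "bias_slope", "nmae"))
  lab <- rbinom(40, 1, 0.5)
  score <- plogis(lab + rnorm(40))
  rep2 <- evaluationReport(lab, score, task = "classification")
  expect_true(all(c("accuracy", "precision", "recall", "f1", "fpr",
                    "auroc") %in% names(rep2)))
})
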