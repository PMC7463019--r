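# Evaluation statistics for drug-sensitivity regression and classification:
# normalized errors, correlation, bias angle, confusion-table metrics,
# AUROC, bootstrap gap statistics and robustness fractions, confidence
# intervals, McNemar tests, residual-regression bias correction, and
# constrained linear stacking.

checkPair <- function(y, yhat) {
  if (length(y) != length(yhat))
    stopf("observed and predicted lengths differ (%d vs %d)", length(y),
          length(yhat))
  if (length(y) < 2) stopf("need at least 2 observations")
  invisible(NULL)
}

#' Normalized root mean square error
#'
#' Ratio of the model RMSE to the RMSE of the intercept-only (mean)
#' predictor: \code{||y - yhat|| / ||y - mean(y)||}. Equals 1 for the mean
#' predictor and 0 for perfect prediction.
#'
#' @param y observed responses
#' @param yhat predicted responses
#' @return scalar NRMSE
#' @export
nrmse <- function(y, yhat) {
  checkPair(y, yhat)
  denom <- sqrt(sum((y - mean(y))^2))
  if (denom == 0) stopf("observed responses are constant: NRMSE undefined")
  sqrt(sum((y - yhat)^2)) / denom
}

#' Normalized mean absolute error
#'
#' MAE of the model over the MAE of the mean predictor:
#' \code{sum(|y - yhat|) / sum(|y - mean(y)|)}.
#'
#' @inheritParams nrmse
#' @return scalar NMAE
#' @export
nmae <- function(y, yhat) {
  checkPair(y, yhat)
  denom <- sum(abs(y - mean(y)))
  if (denom == 0) stopf("observed responses are constant: NMAE undefined")
  sum(abs(y - yhat)) / denom
}

#' Pearson correlation between observed and predicted
#'
#' @inheritParams nrmse
#' @return scalar correlation in [-1, 1]
#' @export
pcc <- function(y, yhat) {
  checkPair(y, yhat)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stopf("constant input: correlation undefined")
  stats::cor(y, yhat)
}

#' Prediction bias as the tangent of the bias angle
#'
#' Two conventions are provided because they are not algebraically
#' equivalent. \code{"vector_angle"} (default) takes theta as the angle
#' between the observation vector y and the residual vector y - yhat,
#' \code{theta = acos(y' (y - yhat) / (||y|| ||y - yhat||))}, bias =
#' tan(theta). \code{"ols_slope"} takes theta as the arctangent of the
#' least-squares slope of the residuals regressed on y (the fitted-line
#' reading), so bias equals that slope. A zero residual vector (perfect
#' prediction) returns bias 0 with a warning rather than erroring.
#'
#' @inheritParams nrmse
#' @param mode \code{"vector_angle"} or \code{"ols_slope"}
#' @return list with \code{bias} and \code{thetaDegrees}
#' @export
biasAngle <- function(y, yhat, mode = c("vector_angle", "ols_slope")) {
  checkPair(y, yhat)
  mode <- match.arg(mode)
  eps <- y - yhat
  if (mode == "vector_angle") {
    ny <- sqrt(sum(y^2))
    ne <- sqrt(sum(eps^2))
    if (ny == 0) stopf("zero observation vector: angle undefined")
    if (ne == 0) {
      warning("zero residual vector (perfect prediction); reporting bias 0")
      return(list(bias = 0, thetaDegrees = 0))
    }
    ct <- min(1, max(-1, sum(y * eps) / (ny * ne)))
    theta <- acos(ct) * 180 / pi
    list(bias = tan(theta * pi / 180), thetaDegrees = theta)
  } else {
    if (stats::sd(y) == 0) stopf("constant observed responses: slope undefined")
    slope <- unname(stats::coef(stats::lm(eps ~ y))[2])
    list(bias = slope, thetaDegrees = atan(slope) * 180 / pi)
  }
}

#' Confusion counts from labelled predictions
#'
#' @param actual binary (0/1 or logical) true labels
#' @param predicted binary predicted labels
#' @return named integer vector (TP, TN, FP, FN)
#' @export
confusionCounts <- function(actual, predicted) {
  actual <- as.integer(as.logical(actual))
  predicted <- as.integer(as.logical(predicted))
  checkPair(actual, predicted)
  c(TP = sum(actual == 1 & predicted == 1),
    TN = sum(actual == 0 & predicted == 0),
    FP = sum(actual == 0 & predicted == 1),
    FN = sum(actual == 1 & predicted == 0))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall, F1 and false-positive rate from the four
#' confusion-table counts. A metric whose denominator is zero is returned
#' as \code{NA} (flagged per field) rather than erroring.
#'
#' @param counts named vector with TP, TN, FP, FN (see [confusionCounts()])
#' @return named list of metrics in [0,1] (or \code{NA} when undefined)
#' @export
classificationMetrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (any(c(tp, tn, fp, fn) < 0)) stopf("counts must be nonnegative")
  total <- tp + tn + fp + fn
  if (total == 0) stopf("empty confusion table")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  list(accuracy = (tp + tn) / total,
       precision = precision,
       recall = recall,
       f1 = safe(2 * tp, 2 * tp + fp + fn),
       fpr = safe(fp, fp + tn))
}

#' Area under the ROC curve
#'
#' Rank-statistic form (equivalent to the Mann-Whitney U), ties averaged.
#'
#' @param labels binary true labels (both classes must be present)
#' @param scores real-valued scores (higher = more positive)
#' @return AUROC in [0, 1]
#' @export
auroc <- function(labels, scores) {
  labels <- as.logical(labels)
  checkPair(labels, scores)
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

bootMetricValue <- function(metric, y, yhat) {
  switch(metric,
    nrmse = if (stats::sd(y) == 0) NA_real_ else nrmse(y, yhat),
    nmae = if (sum(abs(y - mean(y))) == 0) NA_real_ else nmae(y, yhat),
    pcc = if (stats::sd(y) == 0 || stats::sd(yhat) == 0) NA_real_
          else stats::cor(y, yhat),
    bias = {
      ny <- sqrt(sum(y^2)); ne <- sqrt(sum((y - yhat)^2))
      if (ny == 0) NA_real_
      else if (ne == 0) 0
      else tan(acos(min(1, max(-1, sum(y * (y - yhat)) / (ny * ne)))))
    },
    stopf("unknown metric '%s'", metric))
}

# TRUE when value a is better than b under the metric's orientation.
metricBetter <- function(metric, a, b) {
  if (is.na(a) || is.na(b)) return(FALSE)
  if (metric == "pcc") a > b else a < b
}

#' Bootstrap gap statistics against a null model
#'
#' For each bootstrap replicate, test samples are resampled with
#' replacement; the model's metric is computed on its predictions and a
#' null metric on predictions drawn with replacement from the training
#' responses. Each metric's pooled model/null distribution is then split by
#' 1-D k-means (k = 2, initialised at the two distribution means, at most
#' 100 iterations); the distance between the two centroids is the gap.
#'
#' @param yTest observed test responses
#' @param yPred model predictions on the test set
#' @param yTrain training responses (the null model's sampling distribution)
#' @param metrics which metrics to process
#' @param reps bootstrap replicates (10000 for reported results; reduce for
#'   interactive use)
#' @param seed integer seed
#' @return named list per metric: \code{model} and \code{null} bootstrap
#'   distributions, \code{centroids} (sorted), and \code{gap}
#' @export
gapStatistics <- function(yTest, yPred, yTrain,
                          metrics = c("nrmse", "pcc", "bias"),
                          reps = 10000, seed = 1L) {
  checkPair(yTest, yPred)
  if (length(yTrain) < 1) stopf("empty training responses")
  if (reps < 2) stopf("need at least 2 bootstrap replicates")
  n <- length(yTest)
  withSeed(seed, {
    modelDist <- matrix(NA_real_, reps, length(metrics),
                        dimnames = list(NULL, metrics))
    nullDist <- modelDist
    for (r in seq_len(reps)) {
      idx <- sample.int(n, replace = TRUE)
      yb <- yTest[idx]
      pb <- yPred[idx]
      nullPred <- sample(yTrain, n, replace = TRUE)
      for (mname in metrics) {
        modelDist[r, mname] <- bootMetricValue(mname, yb, pb)
        nullDist[r, mname] <- bootMetricValue(mname, yb, nullPred)
      }
    }
    out <- list()
    for (mname in metrics) {
      pool <- c(modelDist[, mname], nullDist[, mname])
      pool <- pool[is.finite(pool)]
      m1 <- mean(modelDist[, mname], na.rm = TRUE)
      m2 <- mean(nullDist[, mname], na.rm = TRUE)
      centers <- if (abs(m1 - m2) < 1e-12) c(m1, m2 + 1e-9) else c(m1, m2)
      km <- suppressWarnings(
        stats::kmeans(pool, centers = matrix(centers, 2, 1), iter.max = 100))
      cents <- sort(as.vector(km$centers))
      out[[mname]] <- list(model = modelDist[, mname],
                           null = nullDist[, mname],
                           centroids = cents,
                           gap = diff(cents))
    }
    out
  })
}

#' Bootstrap robustness fraction
#'
#' Fraction of bootstrap replicates in which prediction set A is strictly
#' better than B under the chosen metric (lower NRMSE/NMAE/bias, higher
#' PCC). Ties count as non-wins, so identical predictions give 0.
#'
#' @param yTest observed test responses
#' @param predA,predB two prediction vectors on the same test set
#' @param metric one of \code{"nrmse"}, \code{"nmae"}, \code{"pcc"},
#'   \code{"bias"}
#' @param reps bootstrap replicates
#' @param seed integer seed
#' @return fraction in [0, 1]
#' @export
robustness <- function(yTest, predA, predB, metric = "nrmse", reps = 10000,
                       seed = 1L) {
  checkPair(yTest, predA)
  checkPair(yTest, predB)
  metric <- match.arg(metric, c("nrmse", "nmae", "pcc", "bias"))
  n <- length(yTest)
  withSeed(seed, {
    wins <- 0L
    for (r in seq_len(reps)) {
      idx <- sample.int(n, replace = TRUE)
      yb <- yTest[idx]
      a <- bootMetricValue(metric, yb, predA[idx])
      b <- bootMetricValue(metric, yb, predB[idx])
      if (metricBetter(metric, a, b)) wins <- wins + 1L
    }
    wins / reps
  })
}

#' Jackknife-after-bootstrap style percentile confidence interval
#'
#' Bootstrap sets are drawn from the complete set of test samples and the
#' (alpha/2, 1 - alpha/2) percentiles of the resulting metric distribution
#' form the interval.
#'
#' @inheritParams robustness
#' @param yPred predictions on the test set
#' @param alpha 1 - coverage (default 0.05 for a 95\% CI)
#' @return numeric vector \code{c(lower, upper)}
#' @export
jabCI <- function(yTest, yPred, metric = "nrmse", reps = 1000, alpha = 0.05,
                  seed = 1L) {
  checkPair(yTest, yPred)
  metric <- match.arg(metric, c("nrmse", "nmae", "pcc", "bias"))
  if (reps < 100) stopf("need at least 100 bootstrap replicates")
  n <- length(yTest)
  withSeed(seed, {
    vals <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(n, replace = TRUE)
      bootMetricValue(metric, yTest[idx], yPred[idx])
    }, numeric(1))
    vals <- vals[is.finite(vals)]
    unname(stats::quantile(vals, c(alpha / 2, 1 - alpha / 2)))
  })
}

#' Binomial proportion confidence interval
#'
#' Normal-approximation interval \code{p +- z sqrt(p(1-p)/n)}, clipped to
#' [0,1]; the Wilson score interval is available as an option.
#'
#' @param successes number of successes
#' @param n number of trials (> 0)
#' @param alpha 1 - coverage
#' @param method \code{"normal"} (default) or \code{"wilson"}
#' @return numeric vector \code{c(lower, upper)}
#' @export
binomialCI <- function(successes, n, alpha = 0.05,
                       method = c("normal", "wilson")) {
  method <- match.arg(method)
  if (n <= 0) stopf("n must be positive")
  if (successes < 0 || successes > n) stopf("successes must lie in [0, n]")
  phat <- successes / n
  z <- stats::qnorm(1 - alpha / 2)
  if (method == "normal") {
    half <- z * sqrt(phat * (1 - phat) / n)
    c(max(0, phat - half), min(1, phat + half))
  } else {
    centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(max(0, centre - half), min(1, centre + half))
  }
}

#' McNemar test of paired classifier disagreement
#'
#' Builds the 2x2 disagreement table from per-sample correctness of two
#' classifiers. With fewer than 25 discordant pairs an exact two-sided
#' binomial test is used; otherwise the chi-square test with continuity
#' correction. No discordant pairs gives p = 1 with a warning.
#'
#' @param correctA,correctB logical (or 0/1) per-sample correctness vectors
#' @return list with \code{statistic} (chi-square, or \code{NA} for the
#'   exact branch), \code{pValue}, discordant counts \code{b} and \code{c},
#'   and \code{method}
#' @export
mcnemarTest <- function(correctA, correctB) {
  correctA <- as.logical(correctA)
  correctB <- as.logical(correctB)
  checkPair(correctA, correctB)
  b <- sum(correctA & !correctB)
  cc <- sum(!correctA & correctB)
  if (b + cc == 0) {
    warning("no discordant pairs; returning p = 1")
    return(list(statistic = NA_real_, pValue = 1, b = b, c = cc,
                method = "degenerate"))
  }
  if (b + cc < 25) {
    p <- stats::binom.test(b, b + cc, p = 0.5)$p.value
    list(statistic = NA_real_, pValue = p, b = b, c = cc, method = "exact")
  } else {
    tab <- matrix(c(sum(correctA & correctB), b, cc,
                    sum(!correctA & !correctB)), 2, 2, byrow = TRUE)
    ht <- stats::mcnemar.test(tab, correct = TRUE)
    list(statistic = unname(ht$statistic), pValue = ht$p.value, b = b,
         c = cc, method = "chi-square")
  }
}

#' Residual-regression bias correction
#'
#' Fits the linear residual trend \code{eps = alpha + beta * y} on a set
#' where observations are known (typically the validation set). At
#' application time the observed response is unknown, so the fitted trend
#' is inverted through the prediction: solving
#' \code{y = yhat + alpha + beta * y} for y gives the implied observation
#' \code{(yhat + alpha) / (1 - beta)}, which is the corrected prediction.
#' With \code{regressor = "observed"} (only possible when the new set's
#' observations are supplied) the correction uses y directly, which makes
#' the post-correction residual slope on the fitting set exactly zero.
#'
#' @param fitY,fitPred observed and predicted responses of the fitting set
#' @param newPred predictions to correct (default: the fitting set's)
#' @param regressor \code{"prediction"} (default; y unknown at test time)
#'   or \code{"observed"}
#' @param newY observed responses of the new set, required for
#'   \code{regressor = "observed"}
#' @return corrected prediction vector
#' @export
bc1Correct <- function(fitY, fitPred, newPred = fitPred,
                       regressor = c("prediction", "observed"), newY = NULL) {
  checkPair(fitY, fitPred)
  regressor <- match.arg(regressor)
  if (stats::sd(fitY) == 0) stopf("constant fitting responses")
  fit <- stats::lm((fitY - fitPred) ~ fitY)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (regressor == "observed") {
    if (is.null(newY)) stopf("regressor = 'observed' requires newY")
    newPred + a + b * newY
  } else {
    if (abs(1 - b) < 1e-8)
      stopf("residual slope too close to 1; implied-observation correction unstable")
    (newPred + a) / (1 - b)
  }
}

# Exact least squares on the probability simplex (w >= 0, sum w = 1) by
# support enumeration; model counts are small so 2^M subsets is cheap.
# Subsets are visited by increasing size then lexicographically, and a
# candidate must strictly improve, so exact single-model fits win ties.
simplexLsq <- function(a, y) {
  mtot <- ncol(a)
  best <- NULL
  bestErr <- Inf
  for (size in seq_len(mtot)) {
    for (sel in utils::combn(mtot, size, simplify = FALSE)) {
      asub <- a[, sel, drop = FALSE]
      # minimise ||y - asub w||^2 s.t. sum w = 1 via KKT system
      g <- crossprod(asub)
      kkt <- rbind(cbind(2 * g, rep(1, size)), c(rep(1, size), 0))
      rhs <- c(2 * crossprod(asub, y), 1)
      w <- tryCatch(solve(kkt, rhs)[seq_len(size)],
                    error = function(e) NULL)
      if (is.null(w) || any(w < -1e-10)) next
      w <- pmax(w, 0)
      w <- w / sum(w)
      err <- sum((y - asub %*% w)^2)
      if (err < bestErr - 1e-12) {
        bestErr <- err
        best <- numeric(mtot)
        best[sel] <- w
      }
    }
  }
  if (is.null(best)) {
    # fall back to the best single model
    errs <- colSums((a - y)^2)
    best <- numeric(mtot)
    best[which.min(errs)] <- 1
  }
  best
}

#' Linear model stacking with simplex-constrained weights
#'
#' Combines several models' predictions with nonnegative weights summing to
#' one, chosen to minimise squared error of the stacked prediction on the
#' validation set. Because single models are vertices of the feasible set,
#' the stacked validation error never exceeds the best single model's.
#'
#' @param yVal observed validation responses
#' @param valPreds n x M matrix (or list) of validation predictions, one
#'   column per model
#' @param testPreds n' x M matrix (or list) of test predictions in the same
#'   model order; default \code{valPreds}
#' @return list with \code{weights} (length M, sums to 1) and
#'   \code{stacked} (weighted test prediction)
#' @export
stackPredictions <- function(yVal, valPreds, testPreds = valPreds) {
  if (is.list(valPreds) && !is.matrix(valPreds))
    valPreds <- do.call(cbind, valPreds)
  if (is.list(testPreds) && !is.matrix(testPreds))
    testPreds <- do.call(cbind, testPreds)
  valPreds <- as.matrix(valPreds)
  testPreds <- as.matrix(testPreds)
  if (ncol(valPreds) < 1) stopf("need at least one model")
  if (nrow(valPreds) != length(yVal))
    stopf("validation predictions and responses disagree in length")
  if (ncol(testPreds) != ncol(valPreds))
    stopf("validation and test prediction sets disagree in model count")
  w <- simplexLsq(valPreds, yVal)
  list(weights = w, stacked = as.vector(testPreds %*% w))
}

#' Regression / classification evaluation report
#'
#' Convenience wrapper collecting the standard report for one prediction
#' set: NRMSE, PCC, bias (both conventions) and NMAE for regression;
#' confusion metrics and AUROC for classification.
#'
#' @param y observed responses (binary labels for classification)
#' @param yhat predictions (scores/probabilities for classification)
#' @param task \code{"regression"} or \code{"classification"}
#' @param threshold score threshold for labelling (classification only)
#' @return named list of metrics
#' @export
evaluationReport <- function(y, yhat, task = c("regression", "classification"),
                             threshold = 0.5) {
  task <- match.arg(task)
  if (task == "regression") {
    ba <- biasAngle(y, yhat)
    list(nrmse = nrmse(y, yhat), pcc = pcc(y, yhat), bias = ba$bias,
         theta_degrees = ba$thetaDegrees,
         bias_slope = biasAngle(y, yhat, "ols_slope")$bias,
         nmae = nmae(y, yhat))
  } else {
    cm <- classificationMetrics(confusionCounts(y, yhat >= threshold))
    c(cm, list(auroc = auroc(y, yhat)))
  }
}
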