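# Synthetic benchmark: Gaussian-process-correlated features with a stated
# fraction of spurious (zero-weight) features and linear targets normalized
# to [0,1]. This generator defines the study conditions for every
# distance-preservation and model-comparison check in the package.

#' Simulate the Gaussian-process benchmark dataset
#'
#' Feature rows are i.i.d. draws from N(0, Sigma) with the stationary
#' covariance Sigma_ij = gamma^|i-j| over a lexicographic feature ordering
#' (exact multivariate normal via Cholesky). A random subset of
#' \code{round(spuriousFrac * P)} features receives weight exactly zero;
#' the remaining weights are standard-normal draws resampled away from zero.
#' Targets are y = X w, min-max normalized to [0,1] (no noise term by
#' default). Features are min-max normalized to [0,1] in the returned table
#' for image rendering; the unnormalized draw is kept in \code{raw}.
#'
#' @param N number of samples (>= 2)
#' @param P number of features (>= 2)
#' @param gamma lag-decay of the feature covariance, |gamma| < 1
#' @param spuriousFrac fraction of zero-weight features in [0,1]
#' @param seed integer seed
#' @param noiseSd optional additive Gaussian noise on the pre-normalization
#'   targets (default 0: the benchmark is noiseless)
#' @return a [SyntheticDataset-class]
#' @examples
#' ds <- simulateDataset(50, 20, gamma = 0.7, spuriousFrac = 0.2, seed = 1)
#' sum(ds@spuriousMask)  # 4
#' @export
simulateDataset <- function(N, P, gamma = 0.7, spuriousFrac = 0.2,
                            seed = 1L, noiseSd = 0) {
  if (N < 2 || P < 2) stopf("need N >= 2 and P >= 2")
  if (abs(gamma) >= 1) stopf("gamma must satisfy |gamma| < 1, got %g", gamma)
  if (spuriousFrac < 0 || spuriousFrac > 1)
    stopf("spuriousFrac must lie in [0,1]")
  withSeed(seed, {
    sigma <- gamma^abs(outer(seq_len(P), seq_len(P), "-"))
    cf <- chol(sigma)
    raw <- matrix(stats::rnorm(N * P), N, P) %*% cf
    nSpur <- round(spuriousFrac * P)
    mask <- rep(FALSE, P)
    if (nSpur > 0) mask[sample.int(P, nSpur)] <- TRUE
    w <- numeric(P)
    nLive <- P - nSpur
    if (nLive > 0) {
      wr <- stats::rnorm(nLive)
      while (any(abs(wr) < 1e-8)) wr[abs(wr) < 1e-8] <- stats::rnorm(
        sum(abs(wr) < 1e-8))
      w[!mask] <- wr
    }
    y0 <- as.vector(raw %*% w)
    if (noiseSd > 0) y0 <- y0 + stats::rnorm(N, sd = noiseSd)
    y <- minMax(y0)
    colnames(raw) <- paste0("F", seq_len(P))
    rownames(raw) <- paste0("S", seq_len(N))
    tab <- normalizeFeatures(featureTable(raw))
    new("SyntheticDataset", table = tab, raw = raw, y = y, weights = w,
        spuriousMask = mask, gamma = gamma, seed = as.integer(seed))
  })
}

#' Random train / validation / test split
#'
#' Disjoint, exhaustive, seeded index partition (default 80/10/10). Sizes
#' are \code{floor(fraction * N)} for the first two segments; the remainder
#' goes to the test segment.
#'
#' @param n number of samples, or a [SyntheticDataset-class]
#' @param fractions length-3 vector summing to 1
#' @param seed integer seed
#' @return list with integer index vectors \code{train}, \code{validation},
#'   \code{test}
#' @export
trainValTestSplit <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (is(n, "SyntheticDataset")) n <- nSamples(n@table)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stopf("fractions must be three numbers summing to 1")
  withSeed(seed, {
    perm <- sample.int(n)
    nTrain <- floor(fractions[1] * n)
    nVal <- floor(fractions[2] * n)
    list(train = sort(perm[seq_len(nTrain)]),
         validation = sort(perm[nTrain + seq_len(nVal)]),
         test = sort(perm[(nTrain + nVal + 1):n]))
  })
}

#' Write a synthetic dataset to disk
#'
#' Feature table CSV, targets CSV and a JSON manifest (N, P, gamma,
#' spurious fraction, seed).
#'
#' @param ds a [SyntheticDataset-class]
#' @param dir output directory (created if absent)
#' @return invisibly, the directory
#' @export
writeSyntheticDataset <- function(ds, dir) {
  stopifnot(is(ds, "SyntheticDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeFeatureTable(ds@table, file.path(dir, "X.csv"))
  utils::write.csv(data.frame(id = sampleIds(ds@table), y = ds@y),
                   file.path(dir, "y.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(N = nSamples(ds@table), P = nFeatures(ds@table), gamma = ds@gamma,
         spurious_frac = mean(ds@spuriousMask), seed = ds@seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
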