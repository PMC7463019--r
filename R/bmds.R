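# Bayesian metric MDS on the unit square.
#
# Model: observed pairwise feature distances d_jk are truncated-normal
# around the latent 2D distances delta_jk = ||s_j - s_k||,
#   d_jk ~ N(delta_jk, sigma^2) I(d_jk > 0),
# locations s uniform on [0,1]^2, sigma^2 ~ IG(a, b). The unnormalised log
# posterior over (s, sigma^2) is
#   -(q/2 + a + 1) log sigma^2 - SS/(2 sigma^2)
#     - sum_{j<k} log Phi(delta_jk / sigma) - b / sigma^2,
# with q = choose(p, 2) and SS = sum_{j<k} (d_jk - delta_jk)^2. Locations are
# updated by Metropolis-in-Gibbs with reflected Gaussian proposals; sigma^2
# uses the large-q inverse-gamma approximation of its full conditional.

#' Pairwise distances induced by a LocationSet
#'
#' The estimated true distances: Euclidean distances between the 2D feature
#' locations. When the locations are the sampler's point estimate, this is
#' the benchmark matrix the hill climb optimises against.
#'
#' @param loc a [LocationSet-class]
#' @return a [DistanceMatrix-class]
#' @export
locationDistances <- function(loc) {
  stopifnot(is(loc, "LocationSet"))
  distanceMatrix(as.matrix(stats::dist(coords(loc))),
                 labels = featureNames(loc))
}

# Fold a coordinate back into [0,1] by reflection at the boundaries.
reflectUnit <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

#' Construct a BmdsState with its log posterior filled in
#'
#' @param locations a [LocationSet-class]
#' @param sigma2 positive noise variance
#' @param d observed [DistanceMatrix-class]
#' @param cfg a [BmdsConfig-class]
#' @return a [BmdsState-class]
#' @export
bmdsState <- function(locations, sigma2, d, cfg) {
  st <- new("BmdsState", locations = locations, sigma2 = sigma2,
            logPost = 0)
  st@logPost <- logPosterior(st, d, cfg)
  st
}

#' Unnormalised log posterior of the Bayesian MDS model
#'
#' Includes the truncation penalty sum log Phi(delta/sigma) and the
#' inverse-gamma prior term.
#'
#' @param state a [BmdsState-class]
#' @param d observed [DistanceMatrix-class] (labels must match the state)
#' @param cfg a [BmdsConfig-class]
#' @return scalar log posterior (up to an additive constant)
#' @export
logPosterior <- function(state, d, cfg) {
  stopifnot(is(state, "BmdsState"), is(d, "DistanceMatrix"),
            is(cfg, "BmdsConfig"))
  if (state@sigma2 <= 0) stopf("sigma2 must be positive")
  if (!identical(featureNames(state@locations), featureNames(d)))
    stopf("state locations and distance matrix label mismatch")
  s2 <- state@sigma2
  delta <- as.matrix(stats::dist(coords(state@locations)))
  dU <- upperTri(d@.Data)
  deltaU <- upperTri(delta)
  q <- length(dU)
  ss <- sum((dU - deltaU)^2)
  lphi <- sum(stats::pnorm(deltaU / sqrt(s2), log.p = TRUE))
  -(q / 2 + cfg@a + 1) * log(s2) - ss / (2 * s2) - lphi - cfg@b / s2
}

#' Gibbs draw of the noise variance
#'
#' One draw from the approximate full conditional
#' IG(q/2 + a, sum((d - delta)^2)/2 + b); the truncation term is dropped
#' from this conditional (large-q approximation), though it remains in the
#' Metropolis ratio for the locations.
#'
#' @param d observed [DistanceMatrix-class]
#' @param locations current [LocationSet-class]
#' @param cfg a [BmdsConfig-class]
#' @return one positive draw of sigma^2
#' @export
sampleSigma2 <- function(d, locations, cfg) {
  stopifnot(is(d, "DistanceMatrix"), is(locations, "LocationSet"))
  delta <- as.matrix(stats::dist(coords(locations)))
  ss <- sum((upperTri(d@.Data) - upperTri(delta))^2)
  q <- nrow(d@.Data) * (nrow(d@.Data) - 1) / 2
  1 / stats::rgamma(1, shape = q / 2 + cfg@a, rate = ss / 2 + cfg@b)
}

#' One Metropolis update of a single feature location
#'
#' Proposes s_j' = s_j + Gaussian step, reflected into the unit square, and
#' accepts with the Metropolis ratio of the full posterior (including the
#' truncation term).
#'
#' @param state a [BmdsState-class]
#' @param j feature index (1-based)
#' @param d observed [DistanceMatrix-class]
#' @param cfg a [BmdsConfig-class]
#' @return updated [BmdsState-class] with refreshed logPost
#' @export
metropolisUpdateLocation <- function(state, j, d, cfg) {
  stopifnot(is(state, "BmdsState"))
  s <- coords(state@locations)
  p <- nrow(s)
  if (j < 1 || j > p) stopf("feature index %d out of range 1..%d", j, p)
  prop <- reflectUnit(s[j, ] + stats::rnorm(2, sd = cfg@proposalSd))
  dm <- d@.Data
  sig <- sqrt(state@sigma2)
  others <- setdiff(seq_len(p), j)
  oldDelta <- sqrt((s[others, 1] - s[j, 1])^2 + (s[others, 2] - s[j, 2])^2)
  newDelta <- sqrt((s[others, 1] - prop[1])^2 + (s[others, 2] - prop[2])^2)
  dj <- dm[others, j]
  dLp <- (-sum((dj - newDelta)^2) + sum((dj - oldDelta)^2)) /
    (2 * state@sigma2) -
    sum(stats::pnorm(newDelta / sig, log.p = TRUE)) +
    sum(stats::pnorm(oldDelta / sig, log.p = TRUE))
  if (is.finite(dLp) && log(stats::runif(1)) < dLp) {
    s[j, ] <- prop
    state@locations <- locationSet(s)
    state@logPost <- state@logPost + dLp
  }
  state
}

#' Run the Bayesian MDS sampler
#'
#' Each sweep performs one Metropolis update of every feature location
#' followed by one Gibbs draw of sigma^2. The point estimate is the visited
#' state of maximal log posterior (a mode proxy); thinned post-burn-in
#' location draws are retained for data augmentation.
#'
#' @param d observed [DistanceMatrix-class]
#' @param init initial [LocationSet-class] (labels must match \code{d})
#' @param cfg a [BmdsConfig-class]
#' @return a [BmdsFit-class] with the MAP locations, retained draws and a
#'   per-sweep trace of sigma2 and logPost
#' @examples
#' d <- distanceMatrix(matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3))
#' fit <- runBmds(d, mdsInit(d), bmdsConfig(nIter = 200, burnIn = 100))
#' @export
runBmds <- function(d, init, cfg = bmdsConfig()) {
  stopifnot(is(d, "DistanceMatrix"), is(init, "LocationSet"),
            is(cfg, "BmdsConfig"))
  if (!identical(featureNames(init), featureNames(d)))
    stopf("init labels do not match distance matrix labels")
  p <- nFeatures(d)
  q <- p * (p - 1) / 2
  dm <- d@.Data
  dU <- upperTri(dm)
  labels <- featureNames(d)

  withSeed(cfg@seed, {
    s <- coords(init)
    delta <- as.matrix(stats::dist(s))
    ss <- sum((dU - upperTri(delta))^2)
    # start sigma^2 at the conditional mode given the initial locations
    sigma2 <- (ss / 2 + cfg@b) / (q / 2 + cfg@a + 1)
    sig <- sqrt(sigma2)
    lphi <- sum(stats::pnorm(upperTri(delta) / sig, log.p = TRUE))
    lp <- -(q / 2 + cfg@a + 1) * log(sigma2) - ss / (2 * sigma2) - lphi -
      cfg@b / sigma2

    bestLp <- lp
    bestS <- s
    bestSigma2 <- sigma2
    nKeep <- floor((cfg@nIter - cfg@burnIn) / cfg@thin)
    draws <- vector("list", max(nKeep, 0L))
    nDraw <- 0L
    trace <- data.frame(iteration = seq_len(cfg@nIter), sigma2 = NA_real_,
                        logPost = NA_real_)

    for (it in seq_len(cfg@nIter)) {
      for (j in seq_len(p)) {
        prop <- reflectUnit(s[j, ] + stats::rnorm(2, sd = cfg@proposalSd))
        oldDelta <- delta[, j][-j]
        newDelta <- sqrt((s[-j, 1] - prop[1])^2 + (s[-j, 2] - prop[2])^2)
        dj <- dm[-j, j]
        dSs <- sum((dj - newDelta)^2) - sum((dj - oldDelta)^2)
        dLphi <- sum(stats::pnorm(newDelta / sig, log.p = TRUE)) -
          sum(stats::pnorm(oldDelta / sig, log.p = TRUE))
        dLp <- -dSs / (2 * sigma2) - dLphi
        if (is.finite(dLp) && log(stats::runif(1)) < dLp) {
          s[j, ] <- prop
          newCol <- append(newDelta, 0, after = j - 1)
          delta[, j] <- newCol
          delta[j, ] <- newCol
          ss <- ss + dSs
          lphi <- lphi + dLphi
          lp <- lp - dSs / (2 * sigma2) - dLphi
          if (lp > bestLp) {
            bestLp <- lp; bestS <- s; bestSigma2 <- sigma2
          }
        }
      }
      # Gibbs step for sigma^2 (inverse-gamma approximate conditional)
      sigma2 <- 1 / stats::rgamma(1, shape = q / 2 + cfg@a,
                                  rate = ss / 2 + cfg@b)
      sig <- sqrt(sigma2)
      lphi <- sum(stats::pnorm(upperTri(delta) / sig, log.p = TRUE))
      lp <- -(q / 2 + cfg@a + 1) * log(sigma2) - ss / (2 * sigma2) - lphi -
        cfg@b / sigma2
      if (!is.finite(lp))
        stopf("non-finite log posterior at sweep %d (sigma2 = %g)", it, sigma2)
      if (lp > bestLp) {
        bestLp <- lp; bestS <- s; bestSigma2 <- sigma2
      }
      trace$sigma2[it] <- sigma2
      trace$logPost[it] <- lp
      if (it > cfg@burnIn && (it - cfg@burnIn) %% cfg@thin == 0L) {
        nDraw <- nDraw + 1L
        draws[[nDraw]] <- locationSet(s, labels = labels)
      }
    }

    new("BmdsFit",
        map = locationSet(bestS, labels = labels),
        mapSigma2 = bestSigma2,
        mapLogPost = bestLp,
        draws = draws[seq_len(nDraw)],
        trace = trace,
        config = cfg)
  })
}

#' Evenly spaced posterior location draws
#'
#' Selects k evenly spaced retained draws (the last draw for k = 1; the full
#' list for k = number available). Each draw can seed an alternative pixel
#' map for training-set augmentation.
#'
#' @param fit a [BmdsFit-class], or a plain list of [LocationSet-class] draws
#' @param k number of draws wanted
#' @return list of k [LocationSet-class] objects
#' @export
posteriorDrawMaps <- function(fit, k) {
  draws <- if (is(fit, "BmdsFit")) fit@draws else fit
  n <- length(draws)
  if (k > n) stopf("requested %d draws but only %d retained", k, n)
  if (k < 1) stopf("k must be >= 1")
  idx <- rev(round(seq(n, 1, length.out = k)))
  draws[idx]
}

#' Export a sampler trace to CSV
#' @param fit a [BmdsFit-class]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeBmdsTrace <- function(fit, path) {
  stopifnot(is(fit, "BmdsFit"))
  utils::write.csv(fit@trace, path, row.names = FALSE)
  invisible(path)
}

#' Export a LocationSet to CSV (feature, x, y)
#' @param loc a [LocationSet-class]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeLocations <- function(loc, path) {
  stopifnot(is(loc, "LocationSet"))
  utils::write.csv(data.frame(feature = featureNames(loc), coords(loc),
                              row.names = NULL), path, row.names = FALSE)
  invisible(path)
}
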