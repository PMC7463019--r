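#' @import methods
NULL

# ---------------------------------------------------------------------------
# FeatureTable: n samples x p features, sample IDs as rownames, feature
# names as colnames. All downstream stages (distances, maps, images) key on
# feature names, so uniqueness is enforced here once.
# ---------------------------------------------------------------------------

#' FeatureTable: a samples-by-features matrix with identities
#'
#' Container for the predictor matrix X (n samples x p features), e.g.
#' molecular descriptors per drug or gene expression per cell line.
#' Rownames are sample identifiers, colnames are feature names and must be
#' unique. Missing values are tolerated only before [filterFeatures()];
#' [normalizeFeatures()] requires finite entries.
#'
#' @slot values numeric matrix with rownames (samples) and colnames (features)
#' @export
setClass("FeatureTable", representation(values = "matrix"))

setValidity("FeatureTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("feature names (colnames) must be present and unique")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("sample ids (rownames) must be present and unique")
  TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix (samples x features)
#' @param sampleIds optional character vector of sample identifiers; defaults
#'   to existing rownames or \code{"S1"..."Sn"}
#' @param featureNames optional character vector of feature names; defaults to
#'   existing colnames
#' @return a [FeatureTable-class] object
#' @examples
#' ft <- featureTable(matrix(runif(12), 3, 4))
#' dim(values(ft))
#' @export
featureTable <- function(values, sampleIds = NULL, featureNames = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(sampleIds)) rownames(values) <- as.character(sampleIds)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (!is.null(featureNames)) colnames(values) <- as.character(featureNames)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  new("FeatureTable", values = values)
}

# ---------------------------------------------------------------------------
# DistanceMatrix: symmetric p x p matrix of pairwise feature distances.
# Serves both as the observed d fed to the Bayesian sampler and, when
# derived from a LocationSet, as the benchmark delta-hat for hill climbing.
# ---------------------------------------------------------------------------

#' DistanceMatrix: labelled symmetric pairwise distances
#'
#' A p x p symmetric matrix with zero diagonal and nonnegative entries;
#' dimnames carry the feature labels.
#'
#' @export
setClass("DistanceMatrix", contains = "matrix")

setValidity("DistanceMatrix", function(object) {
  m <- object@.Data
  if (nrow(m) != ncol(m)) return("must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("dimnames must be present and identical on both margins")
  if (any(!is.finite(m))) return("entries must be finite")
  if (any(m < 0)) return("entries must be nonnegative")
  if (any(abs(diag(m)) > 1e-12)) return("diagonal must be zero")
  if (max(abs(m - t(m))) > 1e-8) return("must be symmetric")
  TRUE
})

#' Construct a DistanceMatrix
#'
#' @param m square numeric matrix (symmetrised, diagonal zeroed)
#' @param labels optional feature labels (defaults to existing dimnames)
#' @return a [DistanceMatrix-class]
#' @export
distanceMatrix <- function(m, labels = NULL) {
  m <- as.matrix(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  if (is.null(rownames(m)))
    dimnames(m) <- list(paste0("F", seq_len(nrow(m))),
                        paste0("F", seq_len(nrow(m))))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  new("DistanceMatrix", m)
}

# ---------------------------------------------------------------------------
# LocationSet: continuous feature locations on the unit square.
# ---------------------------------------------------------------------------

#' LocationSet: 2D feature locations on the unit square
#'
#' p x 2 coordinates in [0,1]^2, rownames are feature labels. The latent
#' state of the Bayesian MDS sampler and the input to grid tessellation.
#'
#' @slot coords numeric p x 2 matrix, columns x and y
#' @export
setClass("LocationSet", representation(coords = "matrix"))

setValidity("LocationSet", function(object) {
  s <- object@coords
  if (ncol(s) != 2) return("coords must have two columns")
  if (nrow(s) < 2) return("need at least two features")
  if (is.null(rownames(s)) || anyDuplicated(rownames(s)))
    return("coords must have unique rownames (feature labels)")
  if (any(!is.finite(s))) return("coordinates must be finite")
  if (any(s < -1e-12 | s > 1 + 1e-12))
    return("coordinates must lie in [0,1]^2")
  TRUE
})

#' Construct a LocationSet
#' @param coords p x 2 numeric matrix with feature rownames
#' @param labels optional feature labels
#' @return a [LocationSet-class]
#' @export
locationSet <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  if (!is.null(labels)) rownames(coords) <- labels
  colnames(coords) <- c("x", "y")
  coords[] <- pmin(pmax(coords, 0), 1)
  new("LocationSet", coords = coords)
}

# ---------------------------------------------------------------------------
# BmdsConfig / BmdsState / BmdsFit
# ---------------------------------------------------------------------------

#' BmdsConfig: sampler settings for Bayesian metric MDS
#'
#' Priors and Markov-chain controls. The noise variance prior is
#' sigma^2 ~ IG(a, b) with a > 2, b > 0.
#'
#' @slot a inverse-gamma shape (> 2)
#' @slot b inverse-gamma scale (> 0)
#' @slot nIter total sweeps (each sweep updates all p locations, then sigma^2)
#' @slot burnIn discarded sweeps (< nIter)
#' @slot proposalSd Gaussian Metropolis step scale on the unit square
#' @slot thin keep every thin-th post-burn-in sweep as a posterior draw
#' @slot seed integer seed for the sampler's random stream
#' @export
setClass("BmdsConfig", representation(
  a = "numeric", b = "numeric", nIter = "integer", burnIn = "integer",
  proposalSd = "numeric", thin = "integer", seed = "integer"
))

setValidity("BmdsConfig", function(object) {
  if (object@a <= 2) return("a must be > 2")
  if (object@b <= 0) return("b must be > 0")
  if (object@proposalSd <= 0) return("proposalSd must be > 0")
  if (object@burnIn >= object@nIter) return("burnIn must be < nIter")
  if (object@burnIn < 0 || object@nIter < 1) return("invalid iteration counts")
  if (object@thin < 1) return("thin must be >= 1")
  TRUE
})

#' Construct a BmdsConfig
#'
#' Defaults: a = 3, b = 1, 2000 sweeps with 1000 burn-in, proposal sd 0.05,
#' thinning 10.
#'
#' @param a,b inverse-gamma prior shape (> 2) and scale (> 0) for sigma^2
#' @param nIter,burnIn total and discarded MCMC sweeps
#' @param proposalSd Metropolis proposal standard deviation
#' @param thin thinning interval for retained posterior draws
#' @param seed integer seed
#' @return a [BmdsConfig-class]
#' @export
bmdsConfig <- function(a = 3, b = 1, nIter = 2000, burnIn = 1000,
                       proposalSd = 0.05, thin = 10, seed = 1L) {
  new("BmdsConfig", a = a, b = b, nIter = as.integer(nIter),
      burnIn = as.integer(burnIn), proposalSd = proposalSd,
      thin = as.integer(thin), seed = as.integer(seed))
}

#' BmdsState: one point of the (s, sigma^2) chain
#'
#' @slot locations a [LocationSet-class]
#' @slot sigma2 positive noise variance
#' @slot logPost unnormalised log posterior at this state
#' @export
setClass("BmdsState", representation(
  locations = "LocationSet", sigma2 = "numeric", logPost = "numeric"
))

setValidity("BmdsState", function(object) {
  if (object@sigma2 <= 0) return("sigma2 must be positive")
  TRUE
})

#' BmdsFit: the result of running the Bayesian MDS sampler
#'
#' @slot map the maximum-a-posteriori visited [LocationSet-class]
#' @slot mapSigma2 the sigma^2 of the best visited state
#' @slot mapLogPost the log posterior of the best visited state
#' @slot draws list of thinned post-burn-in location draws
#' @slot trace data.frame with columns iteration, sigma2, logPost
#' @slot config the [BmdsConfig-class] used
#' @export
setClass("BmdsFit", representation(
  map = "LocationSet", mapSigma2 = "numeric", mapLogPost = "numeric",
  draws = "list", trace = "data.frame", config = "BmdsConfig"
))

# ---------------------------------------------------------------------------
# PixelMap: the discrete, injective feature -> pixel assignment.
# ---------------------------------------------------------------------------

#' PixelMap: injective assignment of features to pixels
#'
#' Maps each feature name to a (row, col) pixel (0-based) on a
#' gridRows x gridCols grid; no two features share a pixel.
#'
#' @slot gridRows,gridCols grid dimensions
#' @slot assignment integer p x 2 matrix (columns row, col), feature rownames
#' @export
setClass("PixelMap", representation(
  gridRows = "integer", gridCols = "integer", assignment = "matrix"
))

setValidity("PixelMap", function(object) {
  a <- object@assignment
  if (ncol(a) != 2) return("assignment must have two columns (row, col)")
  if (is.null(rownames(a)) || anyDuplicated(rownames(a)))
    return("assignment rownames (features) must be unique")
  if (any(a < 0) || any(a[, 1] >= object@gridRows) ||
      any(a[, 2] >= object@gridCols))
    return("pixels must lie inside the grid")
  if (anyDuplicated(a[, 1] * object@gridCols + a[, 2]))
    return("assignment must be injective: one feature per pixel")
  if (object@gridRows * object@gridCols < nrow(a))
    return("grid too small for the number of features")
  TRUE
})

#' Construct a PixelMap
#' @param assignment integer p x 2 matrix of 0-based (row, col) with feature
#'   rownames
#' @param gridRows,gridCols grid dimensions
#' @return a [PixelMap-class]
#' @export
pixelMap <- function(assignment, gridRows, gridCols) {
  assignment <- as.matrix(assignment)
  storage.mode(assignment) <- "integer"
  colnames(assignment) <- c("row", "col")
  new("PixelMap", gridRows = as.integer(gridRows),
      gridCols = as.integer(gridCols), assignment = assignment)
}

#' HillClimbReport: bookkeeping for the assignment refinement
#'
#' @slot initialCost,finalCost total absolute distance-discrepancy cost
#'   before and after hill climbing
#' @slot nSweeps number of full row-major sweeps performed
#' @slot costTrace cost after each accepted move (non-increasing)
#' @slot initialCorrelation,finalCorrelation Pearson correlation between
#'   pixel distances and the target distances (monitoring only)
#' @export
setClass("HillClimbReport", representation(
  initialCost = "numeric", finalCost = "numeric", nSweeps = "integer",
  costTrace = "numeric", initialCorrelation = "numeric",
  finalCorrelation = "numeric"
))

setValidity("HillClimbReport", function(object) {
  if (object@finalCost > object@initialCost + 1e-9)
    return("finalCost must not exceed initialCost")
  TRUE
})

#' RefinedMap: end-to-end result of the distance-preserving mapping
#'
#' @slot map the final [PixelMap-class]
#' @slot report the [HillClimbReport-class]
#' @slot fit the [BmdsFit-class] (empty for non-Bayesian initialisers)
#' @slot delta the target [DistanceMatrix-class] (estimated true distances)
#' @export
setClass("RefinedMap", representation(
  map = "PixelMap", report = "HillClimbReport", fit = "BmdsFit",
  delta = "DistanceMatrix"
))

# ---------------------------------------------------------------------------
# ImageSet: rendered per-sample images under a PixelMap.
# ---------------------------------------------------------------------------

#' ImageSet: per-sample images rendered under a pixel map
#'
#' @slot pixels numeric array n x rows x cols; dimnames[[1]] are sample ids
#' @slot nullValue intensity assigned to pixels holding no feature
#' @export
setClass("ImageSet", representation(
  pixels = "array", nullValue = "numeric"
))

setValidity("ImageSet", function(object) {
  if (length(dim(object@pixels)) != 3) return("pixels must be a 3D array")
  if (is.null(dimnames(object@pixels)[[1]]))
    return("pixels must carry sample ids in dimnames[[1]]")
  TRUE
})

# ---------------------------------------------------------------------------
# SyntheticDataset: GP-correlated benchmark with spurious features.
# ---------------------------------------------------------------------------

#' SyntheticDataset: Gaussian-process benchmark with spurious features
#'
#' @slot table normalized [FeatureTable-class] (all values in [0,1])
#' @slot raw the unnormalized N x P Gaussian draw the targets were built from
#' @slot y targets in [0,1]
#' @slot weights P linear weights; exactly zero where spuriousMask is TRUE
#' @slot spuriousMask logical P-vector flagging zero-weight features
#' @slot gamma lag-decay of the feature covariance gamma^|i-j|
#' @slot seed integer seed used
#' @export
setClass("SyntheticDataset", representation(
  table = "FeatureTable", raw = "matrix", y = "numeric", weights = "numeric",
  spuriousMask = "logical", gamma = "numeric", seed = "integer"
))

setValidity("SyntheticDataset", function(object) {
  if (any(object@weights[object@spuriousMask] != 0))
    return("spurious features must have exactly zero weight")
  if (any(object@y < -1e-12 | object@y > 1 + 1e-12))
    return("targets must lie in [0,1]")
  TRUE
})
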