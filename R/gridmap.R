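# Continuous 2D initial embeddings, tessellation onto a square pixel grid
# with at most one feature per pixel, and greedy hill-climbing refinement of
# the assignment against a target distance matrix.

# Translate (and shrink only if necessary) a 2D configuration into [0,1]^2,
# preserving pairwise distances whenever the configuration already fits.
fitUnitSquare <- function(x) {
  x <- as.matrix(x)
  ext <- max(diff(range(x[, 1])), diff(range(x[, 2])), .Machine$double.eps)
  if (ext > 1) x <- x / ext
  for (k in 1:2) {
    r <- range(x[, k])
    x[, k] <- x[, k] - r[1] + (1 - (r[2] - r[1])) / 2
  }
  x
}

#' Classical metric MDS initial embedding
#'
#' Torgerson scaling of the observed distances into two dimensions, placed
#' inside the unit square (distances are preserved unless the configuration
#' is wider than the square, in which case it is shrunk to fit).
#'
#' @param d a [DistanceMatrix-class]
#' @param seed unused (the embedding is deterministic); kept for interface
#'   symmetry with [altInit()]
#' @return a [LocationSet-class]
#' @export
mdsInit <- function(d, seed = 1L) {
  stopifnot(is(d, "DistanceMatrix"))
  if (nFeatures(d) < 2) stopf("need at least 2 features")
  if (max(d@.Data) <= 0) stopf("degenerate distance matrix: all distances zero")
  k <- min(2L, nFeatures(d) - 1L)
  xy <- suppressWarnings(stats::cmdscale(d@.Data, k = k))
  while (ncol(xy) < 2) xy <- cbind(xy, 0)
  locationSet(fitUnitSquare(xy), labels = featureNames(d))
}

# Symmetrised k-nearest-neighbour adjacency from a distance matrix.
knnAdjacency <- function(dm, k) {
  p <- nrow(dm)
  a <- matrix(FALSE, p, p)
  for (i in seq_len(p)) {
    nn <- order(dm[i, ])[2:(k + 1)]
    a[i, nn] <- TRUE
  }
  a | t(a)
}

# Locally linear embedding computed directly from a (Euclidean) distance
# matrix: neighbour Gram matrices are recovered from squared distances.
lleEmbed <- function(dm, k) {
  p <- nrow(dm)
  w <- matrix(0, p, p)
  d2 <- dm^2
  for (i in seq_len(p)) {
    nb <- order(dm[i, ])[2:(k + 1)]
    # Gram of neighbours centred at point i, from distances only
    g <- (outer(d2[i, nb], rep(1, k)) + outer(rep(1, k), d2[i, nb]) -
            d2[nb, nb]) / 2
    g <- g + diag(k) * (1e-3 * sum(diag(g)) / k + 1e-12)
    wi <- solve(g, rep(1, k))
    w[i, nb] <- wi / sum(wi)
  }
  m <- diag(p) - w
  m <- t(m) %*% m
  e <- eigen(m, symmetric = TRUE)
  e$vectors[, c(p - 1, p - 2), drop = FALSE]
}

# Laplacian-eigenmap embedding from a distance matrix (binary kNN graph,
# symmetric normalised Laplacian, bottom nonconstant eigenvectors).
leEmbed <- function(dm, k) {
  p <- nrow(dm)
  a <- knnAdjacency(dm, k) * 1
  deg <- pmax(rowSums(a), 1e-12)
  dmh <- 1 / sqrt(deg)
  lsym <- diag(p) - (dmh * a) %*% diag(dmh)
  e <- eigen((lsym + t(lsym)) / 2, symmetric = TRUE)
  u <- e$vectors[, c(p - 1, p - 2), drop = FALSE]
  u * dmh
}

#' Alternative initial embeddings (ablation variants)
#'
#' Isomap (via \pkg{vegan}), locally linear embedding, Laplacian eigenmaps,
#' or uniform random locations, all returned inside the unit square.
#'
#' @param d a [DistanceMatrix-class]
#' @param method one of \code{"isomap"}, \code{"lle"}, \code{"le"},
#'   \code{"random"}
#' @param kNeighbors neighbourhood size for the graph-based methods
#'   (must be < p)
#' @param seed integer seed (used by \code{"random"})
#' @return a [LocationSet-class]
#' @export
altInit <- function(d, method = c("isomap", "lle", "le", "random"),
                    kNeighbors = 10, seed = 1L) {
  stopifnot(is(d, "DistanceMatrix"))
  method <- match.arg(method)
  p <- nFeatures(d)
  if (method != "random" && kNeighbors >= p)
    stopf("kNeighbors (%d) must be smaller than the number of features (%d)",
          kNeighbors, p)
  xy <- switch(method,
    random = withSeed(seed, matrix(stats::runif(2 * p), p, 2)),
    isomap = {
      im <- vegan::isomap(stats::as.dist(d@.Data), ndim = 2, k = kNeighbors)
      im$points[, 1:2, drop = FALSE]
    },
    lle = lleEmbed(d@.Data, kNeighbors),
    le = leEmbed(d@.Data, kNeighbors))
  if (method == "random")
    return(locationSet(xy, labels = featureNames(d)))
  locationSet(fitUnitSquare(xy), labels = featureNames(d))
}

#' Side of the smallest square grid holding p features
#'
#' \code{ceiling(sqrt(p))}; e.g. 672 descriptor features require a
#' 26 x 26 image.
#'
#' @param p number of features (>= 1)
#' @return integer grid side
#' @examples
#' gridSide(672)  # 26
#' @export
gridSide <- function(p) {
  if (length(p) != 1 || is.na(p) || p < 1) stopf("p must be a positive integer")
  as.integer(ceiling(sqrt(as.numeric(p)) - 1e-9))
}

#' Tessellate continuous locations onto a pixel grid
#'
#' Regular square tessellation of the unit square such that each pixel holds
#' at most one feature: every feature is assigned the pixel containing its
#' location; collisions are resolved deterministically to the nearest free
#' pixel by increasing Chebyshev ring, ties broken in row-then-column order.
#' Features are processed in row-major order of their provisional pixel.
#'
#' @param loc a [LocationSet-class]
#' @param gridRows,gridCols grid dimensions; default: the smallest square
#'   grid holding all features
#' @return an injective [PixelMap-class]
#' @export
assignToGrid <- function(loc, gridRows = NULL, gridCols = NULL) {
  stopifnot(is(loc, "LocationSet"))
  s <- coords(loc)
  p <- nrow(s)
  if (is.null(gridRows)) gridRows <- gridSide(p)
  if (is.null(gridCols)) gridCols <- gridRows
  gridRows <- as.integer(gridRows); gridCols <- as.integer(gridCols)
  if (gridRows * gridCols < p) stopf("grid too small: %d x %d < %d features",
                                     gridRows, gridCols, p)
  # provisional pixel: row indexed top-down (high y = row 0)
  prow <- pmin(pmax(floor((1 - s[, 2]) * gridRows), 0), gridRows - 1)
  pcol <- pmin(pmax(floor(s[, 1] * gridCols), 0), gridCols - 1)
  ord <- order(prow * gridCols + pcol, seq_len(p))
  occ <- matrix(FALSE, gridRows, gridCols)
  out <- matrix(NA_integer_, p, 2,
                dimnames = list(rownames(s), c("row", "col")))
  for (i in ord) {
    r <- prow[i]; cc <- pcol[i]
    if (!occ[r + 1, cc + 1]) {
      out[i, ] <- c(r, cc)
      occ[r + 1, cc + 1] <- TRUE
      next
    }
    placed <- FALSE
    for (ring in seq_len(max(gridRows, gridCols))) {
      rr <- max(0, r - ring):min(gridRows - 1, r + ring)
      ccand <- max(0, cc - ring):min(gridCols - 1, cc + ring)
      for (r2 in rr) {
        for (c2 in ccand) {
          if (max(abs(r2 - r), abs(c2 - cc)) != ring) next
          if (!occ[r2 + 1, c2 + 1]) {
            out[i, ] <- c(r2, c2)
            occ[r2 + 1, c2 + 1] <- TRUE
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (placed) break
    }
    if (!placed) stopf("internal error: no free pixel found")
  }
  pixelMap(out, gridRows, gridCols)
}

# Pairwise pixel-centre distances of a map, rescaled to the unit square
# (index offsets divided by the grid side), in the map's feature order.
pixelDistances <- function(m) {
  side <- max(m@gridRows, m@gridCols)
  as.matrix(stats::dist(m@assignment / side))
}

# Align a DistanceMatrix to a map's feature order; errors on mismatch.
alignDelta <- function(m, delta) {
  f <- featureNames(m)
  if (!setequal(f, featureNames(delta)))
    stopf("pixel map and distance matrix label mismatch")
  delta@.Data[f, f]
}

#' Distance-discrepancy cost of a pixel map
#'
#' Sum over feature pairs of the absolute difference between the pixel-centre
#' distance (grid offsets divided by the grid side, so commensurate with
#' unit-square distances) and the target distances delta-hat.
#'
#' @param m a [PixelMap-class]
#' @param deltaHat target [DistanceMatrix-class] (estimated true distances)
#' @return scalar cost
#' @export
mapCost <- function(m, deltaHat) {
  stopifnot(is(m, "PixelMap"), is(deltaHat, "DistanceMatrix"))
  dm <- alignDelta(m, deltaHat)
  sum(abs(upperTri(pixelDistances(m)) - upperTri(dm)))
}

#' Greedy hill climbing of a pixel assignment
#'
#' Repeated row-major sweeps over occupied pixels. For each central feature,
#' the 8 Moore-neighbourhood pixels are tried: an occupied neighbour means a
#' swap of the two features, an empty one a move. The best candidate is
#' accepted only on strict cost improvement, so the cost trace is strictly
#' decreasing at accepted moves and termination is guaranteed. Sweeps stop
#' when a full sweep accepts nothing or \code{maxSweeps} is reached.
#'
#' @param m starting [PixelMap-class]
#' @param deltaHat target [DistanceMatrix-class]
#' @param maxSweeps sweep budget (default 50)
#' @return list with elements \code{map} (refined [PixelMap-class]) and
#'   \code{report} (a [HillClimbReport-class])
#' @export
hillClimb <- function(m, deltaHat, maxSweeps = 50) {
  stopifnot(is(m, "PixelMap"), is(deltaHat, "DistanceMatrix"))
  dm <- alignDelta(m, deltaHat)
  dmU <- upperTri(dm)
  p <- nFeatures(m)
  rows <- m@gridRows; cols <- m@gridCols
  side <- max(rows, cols)
  pos <- m@assignment  # p x 2, 0-based
  occ <- matrix(0L, rows, cols)
  occ[cbind(pos[, 1] + 1L, pos[, 2] + 1L)] <- seq_len(p)

  # cost of all pairs involving feature f if it sat at (r, c); `skip`
  # excludes the swap partner whose pair term is unchanged by a swap
  rowCost <- function(f, r, c, skip = 0L) {
    dx <- (pos[, 1] - r)^2 + (pos[, 2] - c)^2
    term <- abs(sqrt(dx) / side - dm[, f])
    term[f] <- 0
    if (skip > 0L) term[skip] <- 0
    sum(term)
  }

  pd0 <- upperTri(pixelDistances(m))
  cost <- sum(abs(pd0 - dmU))
  corSafe <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  initCost <- cost
  initCor <- corSafe(pd0, dmU)
  trace <- numeric(0)

  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    improved <- FALSE
    for (pix in 0:(rows * cols - 1L)) {
      r <- pix %/% cols; c <- pix %% cols
      f <- occ[r + 1, c + 1]
      if (f == 0L) next
      bestDelta <- -1e-12
      bestMove <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 0 || r2 >= rows || c2 < 0 || c2 >= cols) next
        g <- occ[r2 + 1, c2 + 1]
        if (g > 0L) {
          delta <- (rowCost(f, r2, c2, g) + rowCost(g, r, c, f)) -
            (rowCost(f, r, c, g) + rowCost(g, r2, c2, f))
        } else {
          delta <- rowCost(f, r2, c2) - rowCost(f, r, c)
        }
        if (delta < bestDelta) {
          bestDelta <- delta
          bestMove <- c(r2, c2, g)
        }
      }
      if (!is.null(bestMove)) {
        r2 <- bestMove[1]; c2 <- bestMove[2]; g <- bestMove[3]
        pos[f, ] <- c(r2, c2)
        occ[r2 + 1, c2 + 1] <- f
        if (g > 0L) {
          pos[g, ] <- c(r, c)
          occ[r + 1, c + 1] <- g
        } else {
          occ[r + 1, c + 1] <- 0L
        }
        cost <- cost + bestDelta
        trace <- c(trace, cost)
        improved <- TRUE
      }
    }
    if (!improved || sweeps >= maxSweeps) break
  }

  outMap <- pixelMap(pos, rows, cols)
  # recompute exactly to avoid accumulated float drift in the report
  finalCost <- mapCost(outMap, deltaHat)
  report <- new("HillClimbReport",
                initialCost = initCost, finalCost = finalCost,
                nSweeps = sweeps, costTrace = trace,
                initialCorrelation = initCor,
                finalCorrelation = corSafe(upperTri(pixelDistances(outMap)),
                                           dmU))
  list(map = outMap, report = report)
}

#' Build a distance-preserving feature map end to end
#'
#' Composes the full pipeline: pairwise feature distances, an initial 2D
#' embedding, Bayesian refinement of the locations on the unit square,
#' tessellation onto the smallest square pixel grid, and hill climbing of
#' the assignment against the estimated true distances (those induced by
#' the Bayesian point-estimate locations). Observed distances are rescaled
#' to maximum 1 before embedding so they are commensurate with unit-square
#' geometry.
#'
#' @param x a preprocessed [FeatureTable-class]
#' @param bmds a [BmdsConfig-class]; its seed drives all sampling
#' @param init initial embedding: \code{"mds"} (default) or one of the
#'   [altInit()] methods
#' @param useBmds if \code{FALSE}, skip the Bayesian stage (ablation mode):
#'   hill climbing then targets the initial embedding's induced distances,
#'   or the observed distances themselves for \code{init = "random"}
#' @param maxSweeps hill-climb sweep budget
#' @param kNeighbors neighbourhood size for graph-based initialisers
#' @param seed integer seed for the random initialiser (Bayesian sampling is
#'   seeded by \code{bmds})
#' @return a [RefinedMap-class]
#' @export
buildRefinedMap <- function(x, bmds = bmdsConfig(),
                            init = c("mds", "isomap", "lle", "le", "random"),
                            useBmds = TRUE, maxSweeps = 50, kNeighbors = 10,
                            seed = 1L) {
  stopifnot(is(x, "FeatureTable"))
  init <- match.arg(init)
  d <- featureDistanceMatrix(x)
  mx <- max(d@.Data)
  if (mx <= 0) stopf("degenerate feature table: all features identical")
  dScaled <- distanceMatrix(d@.Data / mx, labels = featureNames(d))
  loc0 <- if (init == "mds") mdsInit(dScaled)
          else altInit(dScaled, init, kNeighbors = kNeighbors, seed = seed)
  if (useBmds) {
    fit <- runBmds(dScaled, loc0, bmds)
    target <- locationDistances(fit@map)
    mapLoc <- fit@map
  } else {
    fit <- new("BmdsFit", map = loc0, mapSigma2 = NA_real_,
               mapLogPost = NA_real_, draws = list(),
               trace = data.frame(iteration = integer(), sigma2 = numeric(),
                                  logPost = numeric()),
               config = bmds)
    target <- if (init == "random") dScaled else locationDistances(loc0)
    mapLoc <- loc0
  }
  m0 <- assignToGrid(mapLoc)
  hc <- hillClimb(m0, target, maxSweeps = maxSweeps)
  new("RefinedMap", map = hc$map, report = hc$report, fit = fit,
      delta = target)
}

#' Serialize / load a pixel map (CSV assignment + JSON header)
#'
#' @param m a [PixelMap-class]
#' @param path CSV output (feature,row,col); a JSON side-car
#'   \code{<path>.json} records the grid dimensions and any extra metadata
#' @param meta named list of extra metadata (seed, method, ...)
#' @return invisibly, \code{path} (write) or the [PixelMap-class] (read)
#' @export
writePixelMap <- function(m, path, meta = list()) {
  stopifnot(is(m, "PixelMap"))
  utils::write.csv(data.frame(feature = featureNames(m), m@assignment,
                              row.names = NULL), path, row.names = FALSE)
  header <- c(list(grid_rows = m@gridRows, grid_cols = m@gridCols), meta)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePixelMap
#' @export
readPixelMap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  header <- jsonlite::read_json(paste0(path, ".json"))
  a <- as.matrix(df[, c("row", "col")])
  rownames(a) <- df$feature
  pixelMap(a, header$grid_rows, header$grid_cols)
}

#' Export a hill-climb cost trace to CSV
#' @param report a [HillClimbReport-class]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeHillClimbTrace <- function(report, path) {
  stopifnot(is(report, "HillClimbReport"))
  utils::write.csv(data.frame(move = seq_along(report@costTrace),
                              cost = report@costTrace), path,
                   row.names = FALSE)
  invisible(path)
}
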