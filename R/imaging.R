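# Rendering per-sample feature vectors into images under a PixelMap, the
# random and PCA baseline mappers, and image serialization.

#' Render feature vectors as images
#'
#' One image per sample: the pixel assigned to each feature gets that
#' sample's feature value; pixels holding no feature get \code{nullValue}.
#' Rendering is lossless for mapped features ([imageToVector()] reads the
#' exact values back).
#'
#' @param x a normalized [FeatureTable-class] whose features are all present
#'   in the map
#' @param m a [PixelMap-class]
#' @param nullValue intensity for empty pixels (default 0, neutral for ReLU
#'   convolutions)
#' @return an [ImageSet-class]
#' @export
vectorsToImages <- function(x, m, nullValue = 0) {
  stopifnot(is(x, "FeatureTable"), is(m, "PixelMap"))
  feats <- featureNames(x)
  missing <- setdiff(feats, featureNames(m))
  if (length(missing) > 0)
    stopf("feature(s) missing from pixel map: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  a <- m@assignment[feats, , drop = FALSE]
  n <- nSamples(x)
  px <- array(nullValue, dim = c(n, m@gridRows, m@gridCols),
              dimnames = list(sampleIds(x), NULL, NULL))
  v <- values(x)
  for (j in seq_along(feats))
    px[cbind(seq_len(n), a[j, 1] + 1, a[j, 2] + 1)] <- v[, j]
  new("ImageSet", pixels = px, nullValue = nullValue)
}

#' Read mapped pixels back into feature vectors
#'
#' Inverse of [vectorsToImages()] for the mapped features (exact
#' round-trip).
#'
#' @param images an [ImageSet-class] (or a single rows x cols matrix)
#' @param m the [PixelMap-class] the images were rendered under
#' @return a samples x features matrix in the map's feature order (a plain
#'   vector for a single-image input)
#' @export
imageToVector <- function(images, m) {
  stopifnot(is(m, "PixelMap"))
  a <- m@assignment
  if (is.matrix(images)) {
    if (!all(dim(images) == c(m@gridRows, m@gridCols)))
      stopf("image is %d x %d but map expects %d x %d", nrow(images),
            ncol(images), m@gridRows, m@gridCols)
    return(stats::setNames(images[cbind(a[, 1] + 1, a[, 2] + 1)],
                           featureNames(m)))
  }
  stopifnot(is(images, "ImageSet"))
  px <- images@pixels
  if (!all(dim(px)[2:3] == c(m@gridRows, m@gridCols)))
    stopf("images are %d x %d but map expects %d x %d", dim(px)[2],
          dim(px)[3], m@gridRows, m@gridCols)
  n <- dim(px)[1]
  out <- matrix(NA_real_, n, nrow(a),
                dimnames = list(dimnames(px)[[1]], featureNames(m)))
  for (j in seq_len(nrow(a)))
    out[, j] <- px[cbind(seq_len(n), a[j, 1] + 1, a[j, 2] + 1)]
  out
}

#' Uniformly random injective pixel map
#'
#' The baseline mapper: each feature is assigned a uniformly random distinct
#' pixel on the smallest square grid holding all features.
#'
#' @param featureNames character vector of feature names
#' @param seed integer seed
#' @return a [PixelMap-class]
#' @export
randomMap <- function(featureNames, seed = 1L) {
  p <- length(featureNames)
  if (p < 1) stopf("need at least one feature")
  side <- gridSide(p)
  pix <- withSeed(seed, sample.int(side * side, p)) - 1L
  a <- cbind(row = pix %/% side, col = pix %% side)
  rownames(a) <- featureNames
  pixelMap(a, side, side)
}

#' PCA-based pixel map
#'
#' Each feature's 2D coordinate is its loading pair on the first two
#' principal components of the feature covariance over samples; coordinates
#' are placed in the unit square and tessellated (collisions from coincident
#' loadings are resolved to nearby pixels).
#'
#' @param x a [FeatureTable-class] with at least 3 samples and 2 features
#' @return a [PixelMap-class]
#' @export
pcaMap <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  if (nFeatures(x) < 2) stopf("need at least 2 features")
  pc <- stats::prcomp(values(x), center = TRUE, scale. = FALSE)
  if (ncol(pc$rotation) < 2 || pc$sdev[2] < .Machine$double.eps)
    stopf("feature covariance has fewer than 2 informative components")
  xy <- pc$rotation[, 1:2, drop = FALSE]
  loc <- locationSet(fitUnitSquare(xy), labels = featureNames(x))
  assignToGrid(loc)
}

#' Write an image set as a numeric archive (lossless) with manifest
#'
#' Long-format CSV (sample, row, col, value) plus a JSON manifest with the
#' grid shape, sample ids and null value; full double precision.
#'
#' @param images an [ImageSet-class]
#' @param path CSV output; manifest goes to \code{<path>.json}
#' @return invisibly, \code{path}
#' @export
writeImageSet <- function(images, path) {
  stopifnot(is(images, "ImageSet"))
  d <- dim(images@pixels)
  idx <- expand.grid(sample = seq_len(d[1]), row = seq_len(d[2]) - 1L,
                     col = seq_len(d[3]) - 1L)
  df <- data.frame(sample = dimnames(images@pixels)[[1]][idx$sample],
                   row = idx$row, col = idx$col,
                   value = as.vector(images@pixels))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n = d[1], rows = d[2], cols = d[3],
                            null_value = images@nullValue,
                            sample_ids = dimnames(images@pixels)[[1]]),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeImageSet
#' @export
readImageSet <- function(path) {
  mf <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  px <- array(NA_real_, dim = c(mf$n, mf$rows, mf$cols),
              dimnames = list(mf$sample_ids, NULL, NULL))
  px[cbind(match(df$sample, mf$sample_ids), df$row + 1, df$col + 1)] <-
    df$value
  new("ImageSet", pixels = px, nullValue = mf$null_value)
}

#' Write grayscale PNG previews of an image set
#'
#' 8-bit grayscale previews for visual inspection only (quantised); model
#' training should read the lossless numeric archive instead.
#'
#' @param images an [ImageSet-class] with intensities in [0,1]
#' @param dir output directory (created if absent); one
#'   \code{<sample>.png} per sample
#' @return invisibly, the vector of files written
#' @export
writeImagePngs <- function(images, dir) {
  stopifnot(is(images, "ImageSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- dimnames(images@pixels)[[1]]
  files <- file.path(dir, paste0(ids, ".png"))
  for (i in seq_along(ids)) {
    img <- pmin(pmax(images@pixels[i, , ], 0), 1)
    png::writePNG(img, files[i])
  }
  invisible(files)
}
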