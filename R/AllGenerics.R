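# Accessor generics. `values` / `featureNames` / `sampleIds` mirror the
# conventional assay/rownames/colnames triple for a samples-by-features table.

#' Extract the numeric matrix of a container
#' @param x object
#' @param ... unused
#' @return numeric matrix
#' @export
setGeneric("values", function(x, ...) standardGeneric("values"))

#' Feature labels of a container
#' @param x object
#' @return character vector of feature names
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Sample identifiers of a container
#' @param x object
#' @return character vector of sample ids
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Number of features
#' @param x object
#' @return integer
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Number of samples
#' @param x object
#' @return integer
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' 2D coordinates of a location container
#' @param x object
#' @return p x 2 numeric matrix
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Pixel map of a composite result
#' @param x object
#' @return a [PixelMap-class]
#' @export
setGeneric("pixelMapOf", function(x) standardGeneric("pixelMapOf"))

#' Hill-climb report of a composite result
#' @param x object
#' @return a [HillClimbReport-class]
#' @export
setGeneric("hillClimbReport", function(x) standardGeneric("hillClimbReport"))

#' @rdname values
#' @export
setMethod("values", "FeatureTable", function(x, ...) x@values)

#' @rdname featureNames
#' @export
setMethod("featureNames", "FeatureTable", function(x) colnames(x@values))

#' @rdname featureNames
#' @export
setMethod("featureNames", "DistanceMatrix", function(x) rownames(x@.Data))

#' @rdname featureNames
#' @export
setMethod("featureNames", "LocationSet", function(x) rownames(x@coords))

#' @rdname featureNames
#' @export
setMethod("featureNames", "PixelMap", function(x) rownames(x@assignment))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "FeatureTable", function(x) rownames(x@values))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ImageSet", function(x) dimnames(x@pixels)[[1]])

#' @rdname nFeatures
#' @export
setMethod("nFeatures", "FeatureTable", function(x) ncol(x@values))

#' @rdname nFeatures
#' @export
setMethod("nFeatures", "DistanceMatrix", function(x) nrow(x@.Data))

#' @rdname nFeatures
#' @export
setMethod("nFeatures", "PixelMap", function(x) nrow(x@assignment))

#' @rdname nSamples
#' @export
setMethod("nSamples", "FeatureTable", function(x) nrow(x@values))

#' @rdname nSamples
#' @export
setMethod("nSamples", "ImageSet", function(x) dim(x@pixels)[1])

#' @rdname coords
#' @export
setMethod("coords", "LocationSet", function(x) x@coords)

#' @rdname pixelMapOf
#' @export
setMethod("pixelMapOf", "RefinedMap", function(x) x@map)

#' @rdname hillClimbReport
#' @export
setMethod("hillClimbReport", "RefinedMap", function(x) x@report)

#' Grid dimensions of a pixel map
#' @param x a [PixelMap-class]
#' @return integer vector (rows, cols)
#' @export
gridDim <- function(x) {
  stopifnot(is(x, "PixelMap"))
  c(rows = x@gridRows, cols = x@gridCols)
}

#' 0-based pixel assignment of a map
#' @param x a [PixelMap-class]
#' @return integer p x 2 matrix (row, col) with feature rownames
#' @export
assignment <- function(x) {
  stopifnot(is(x, "PixelMap"))
  x@assignment
}

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d samples x %d features\n",
              nSamples(object), nFeatures(object)))
  cat("  features: ", paste(utils::head(featureNames(object), 4),
                            collapse = ", "),
      if (nFeatures(object) > 4) ", ..." else "", "\n", sep = "")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d features, max distance %.4g\n",
              nFeatures(object), max(object@.Data)))
})

setMethod("show", "LocationSet", function(object) {
  cat(sprintf("LocationSet: %d features on the unit square\n",
              nrow(object@coords)))
})

setMethod("show", "PixelMap", function(object) {
  cat(sprintf("PixelMap: %d features on a %d x %d grid (%d empty pixels)\n",
              nFeatures(object), object@gridRows, object@gridCols,
              object@gridRows * object@gridCols - nFeatures(object)))
})

setMethod("show", "BmdsFit", function(object) {
  cat(sprintf(
    "BmdsFit: %d features, %d retained draws, best logPost %.4f\n",
    nrow(object@map@coords), length(object@draws),
    max(object@trace$logPost)))
})

setMethod("show", "HillClimbReport", function(object) {
  cat(sprintf(
    "HillClimbReport: cost %.4f -> %.4f in %d sweeps (%d accepted moves)\n",
    object@initialCost, object@finalCost, object@nSweeps,
    length(object@costTrace)))
})

setMethod("show", "RefinedMap", function(object) {
  show(object@map)
  show(object@report)
})

setMethod("show", "ImageSet", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageSet: %d images of %d x %d pixels (null value %g)\n",
              d[1], d[2], d[3], object@nullValue))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d samples x %d features, gamma %.2f, %d spurious\n",
    nSamples(object@table), nFeatures(object@table), object@gamma,
    sum(object@spuriousMask)))
})
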