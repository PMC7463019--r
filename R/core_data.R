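# Feature-table ingestion, the two preprocessing rules used throughout
# (discard features with too many zero-or-missing values; min-max normalize
# each feature to [0,1]), and pairwise feature distances.

#' Load a feature table from CSV or TSV
#'
#' Reads a delimited file with a header row of feature names and one ID
#' column. The separator is taken from the file extension (.tsv/.txt = tab,
#' otherwise comma).
#'
#' @param path file path
#' @param idColumn name of the sample-ID column (default: first column)
#' @param sep field separator; \code{NULL} = infer from extension
#' @return a [FeatureTable-class]
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = c("a", "b"), f1 = 1:2, f2 = 3:4), tf,
#'           row.names = FALSE)
#' loadFeatureTable(tf)
#' @export
loadFeatureTable <- function(path, idColumn = NULL, sep = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (anyDuplicated(header))
    stopf("duplicated feature column name(s): %s",
          paste(unique(header[duplicated(header)]), collapse = ", "))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stopf("malformed file %s: %s", path, conditionMessage(e)))
  if (is.null(idColumn)) idColumn <- names(df)[1]
  if (!idColumn %in% names(df))
    stopf("id column '%s' not present in %s", idColumn, path)
  ids <- as.character(df[[idColumn]])
  if (anyDuplicated(ids))
    stopf("duplicated sample id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[setdiff(names(df), idColumn)])
  storage.mode(m) <- "double"
  featureTable(m, sampleIds = ids)
}

#' Write a feature table to CSV
#'
#' Round-trips exactly through [loadFeatureTable()] (values are written with
#' full precision).
#'
#' @param x a [FeatureTable-class]
#' @param path output file
#' @param idColumn name for the sample-ID column
#' @return invisibly, \code{path}
#' @export
writeFeatureTable <- function(x, path, idColumn = "id") {
  stopifnot(is(x, "FeatureTable"))
  df <- data.frame(sampleIds(x), values(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discard features with too many zero-or-missing values
#'
#' Drops every feature whose fraction of entries that are exactly zero or
#' missing strictly exceeds \code{maxBadFrac} (default 0.10, i.e. the
#' ">10% zero or missing" preprocessing rule). Survivor order is preserved.
#'
#' @param x a [FeatureTable-class]
#' @param maxBadFrac tolerated fraction of zero-or-missing entries, in [0,1]
#' @return filtered [FeatureTable-class]
#' @export
filterFeatures <- function(x, maxBadFrac = 0.10) {
  stopifnot(is(x, "FeatureTable"))
  if (maxBadFrac < 0 || maxBadFrac > 1)
    stopf("maxBadFrac must lie in [0,1], got %g", maxBadFrac)
  v <- values(x)
  bad <- colMeans(is.na(v) | (!is.na(v) & v == 0)) > maxBadFrac
  if (all(bad))
    stopf("all %d features exceed the zero-or-missing threshold %g",
          ncol(v), maxBadFrac)
  featureTable(v[, !bad, drop = FALSE])
}

#' Min-max normalize each feature to [0,1]
#'
#' Per-feature affine rescale so that the minimum maps to 0 and the maximum
#' to 1. Constant features map to all-zero rather than erroring, so inert
#' descriptors do not abort a pipeline. Missing or non-finite entries are an
#' error: filtering must happen first, values are never imputed.
#'
#' @param x a [FeatureTable-class]
#' @return normalized [FeatureTable-class]
#' @export
normalizeFeatures <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  v <- values(x)
  if (any(!is.finite(v)))
    stopf("non-finite entries present; run filterFeatures() first, values are never imputed")
  featureTable(apply(v, 2, minMax), sampleIds = sampleIds(x),
               featureNames = featureNames(x))
}

#' Pairwise Euclidean distances between features
#'
#' Each feature is a point in sample space (a column of the table); the
#' result is the p x p Euclidean distance matrix between feature columns,
#' the observed distances d fed to the Bayesian embedding.
#'
#' @param x a [FeatureTable-class] (normalized)
#' @return a [DistanceMatrix-class]
#' @export
featureDistanceMatrix <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  if (nFeatures(x) < 2) stopf("need at least 2 features, got %d", nFeatures(x))
  v <- values(x)
  if (any(!is.finite(v))) stopf("non-finite entries in feature table")
  distanceMatrix(as.matrix(stats::dist(t(v))), labels = featureNames(x))
}

#' Write / read a labelled distance matrix as CSV
#' @param d a [DistanceMatrix-class]
#' @param path file path
#' @return invisibly, \code{path} (write) or the [DistanceMatrix-class] (read)
#' @export
writeDistanceMatrix <- function(d, path) {
  stopifnot(is(d, "DistanceMatrix"))
  utils::write.csv(format(as.data.frame(d@.Data), digits = 17, trim = TRUE),
                   path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  distanceMatrix(m, labels = rownames(m))
}
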