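# Internal helpers shared across modules.

# Evaluate expr under a local RNG seed, restoring the caller's random state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Upper-triangle (j < k) vector of a square matrix, fixed ordering.
upperTri <- function(m) m[upper.tri(m)]

# Min-max rescale a vector to [0,1]; constant vectors map to 0.
minMax <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
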