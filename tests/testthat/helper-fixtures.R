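# Shared fixtures and independent oracles, all built in code.

# Small random feature table with unique names.
makeTable <- function(n = 10, p = 4, seed = 1) {
  set.seed(seed)
  featureTable(matrix(runif(n * p), n, p),
               sampleIds = paste0("s", seq_len(n)),
               featureNames = paste0("f", seq_len(p)))
}

# Equilateral p = 3 distance matrix with side `d`.
equilateral <- function(d = 0.5) {
  m <- matrix(d, 3, 3) - diag(d, 3)
  distanceMatrix(m, labels = c("F1", "F2", "F3"))
}

# Independent term-by-term evaluation of the unnormalised log posterior:
# written directly from the model density, separate from the package path.
oracleLogPost <- function(s, sigma2, dm, a, b) {
  delta <- as.matrix(dist(s))
  dU <- dm[upper.tri(dm)]
  deltaU <- delta[upper.tri(delta)]
  q <- length(dU)
  -(q / 2 + a + 1) * log(sigma2) -
    sum((dU - deltaU)^2) / (2 * sigma2) -
    sum(pnorm(deltaU / sqrt(sigma2), log.p = TRUE)) -
    b / sigma2
}

# All permutations of a small vector (for brute-force assignment oracles).
allPerms <- function(v) {
  if (length(v) == 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(allPerms(v[-i]), function(p) c(v[i], p))))
}

# Brute-force 1-swap local-optimality check over the hill climb's own move
# set: TRUE if no exchange of a feature with any of its 8 Moore-neighbour
# pixels (swap when occupied, move when empty) lowers the cost.
isOneSwapOptimal <- function(m, delta, tol = 1e-9) {
  base <- mapCost(m, delta)
  a <- assignment(m)
  p <- nrow(a)
  gd <- gridDim(m)
  occ <- matrix(0L, gd[1], gd[2])
  occ[cbind(a[, 1] + 1, a[, 2] + 1)] <- seq_len(p)
  for (i in seq_len(p)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- a[i, 1] + dr; c2 <- a[i, 2] + dc
      if (r2 < 0 || r2 >= gd[1] || c2 < 0 || c2 >= gd[2]) next
      j <- occ[r2 + 1, c2 + 1]
      a2 <- a
      if (j > 0L) a2[j, ] <- a[i, ]
      a2[i, ] <- c(r2, c2)
      if (mapCost(pixelMap(a2, gd[1], gd[2]), delta) < base - tol)
        return(FALSE)
    }
  }
  TRUE
}
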