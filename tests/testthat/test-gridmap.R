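test_that("metric MDS initialisation preserves realizable geometry", {
  # two features at distance 0.5 embed at exactly that distance
  d2 <- distanceMatrix(matrix(c(0, 0.5, 0.5, 0), 2), labels = c("a", "b"))
  l2 <- mdsInit(d2)
  expect_equal(as.numeric(dist(coords(l2))), 0.5, tolerance = 1e-9)

  # three equidistant features stay equidistant
  l3 <- mdsInit(equilateral(0.3))
  dd <- as.numeric(dist(coords(l3)))
  expect_lt(max(dd) - min(dd), 1e-6)

  # coordinates always inside the unit square
  d <- featureDistanceMatrix(makeTable(20, 12, seed = 2))
  s <- coords(mdsInit(d))
  expect_true(all(s >= 0 & s <= 1))

  expect_error(mdsInit(distanceMatrix(matrix(0, 3, 3))), "degenerate")
})

test_that("alternative initialisers produce valid unit-square embeddings", {
  d <- featureDistanceMatrix(makeTable(30, 12, seed = 4))

  r1 <- altInit(d, "random", seed = 9)
  r2 <- altInit(d, "random", seed = 9)
  expect_identical(coords(r1), coords(r2))
  expect_false(identical(coords(r1), coords(altInit(d, "random", seed = 10))))

  for (meth in c("isomap", "lle", "le")) {
    l <- altInit(d, meth, kNeighbors = 5)
    expect_s4_class(l, "LocationSet")
    expect_true(all(coords(l) >= 0 & coords(l) <= 1))
  }
  expect_error(altInit(d, "lle", kNeighbors = 12), "smaller")
  expect_error(altInit(d, "umap"))
})

test_that("isomap on an already-2D Euclidean configuration agrees with MDS", {
  set.seed(6)
  pts <- matrix(runif(2 * 25), 25, 2)
  d <- distanceMatrix(as.matrix(dist(pts)), labels = paste0("f", 1:25))
  dm <- as.numeric(dist(coords(mdsInit(d))))
  di <- as.numeric(dist(coords(altInit(d, "isomap", kNeighbors = 20))))
  expect_gt(cor(dm, di), 0.99)   # same geometry up to rigid motion/scale
})

test_that("gridSide returns the smallest square side", {
  expect_identical(gridSide(672), 26L)
  expect_identical(gridSide(4), 2L)
  expect_identical(gridSide(5), 3L)
  expect_identical(gridSide(1), 1L)
  expect_error(gridSide(0), "positive")
})

test_that("tessellation bins locations and forces injectivity", {
  loc <- locationSet(cbind(c(0.1, 0.1, 0.9, 0.9), c(0.1, 0.9, 0.1, 0.9)),
                     labels = paste0("f", 1:4))
  m <- assignToGrid(loc)
  a <- assignment(m)
  # four distinct corner pixels of the 2x2 grid
  expect_equal(sort(paste(a[, 1], a[, 2])), c("0 0", "0 1", "1 0", "1 1"))
  expect_equal(a["f1", ], c(row = 1, col = 0))  # low x, low y = bottom-left
  expect_equal(a["f4", ], c(row = 0, col = 1))

  # coincident locations still get distinct pixels
  loc2 <- locationSet(matrix(0.5, 5, 2), labels = paste0("g", 1:5))
  m2 <- assignToGrid(loc2)
  expect_s4_class(m2, "PixelMap")   # validity enforces injectivity
  expect_equal(nFeatures(m2), 5)

  # p = 5 on a 3x3 grid leaves exactly 4 empty pixels
  gd <- gridDim(m2)
  expect_equal(gd[["rows"]] * gd[["cols"]] - nFeatures(m2), 4)
})

test_that("map cost is the sum of absolute pixel/target discrepancies", {
  a <- cbind(row = c(0, 0, 1, 1), col = c(0, 1, 0, 1))
  rownames(a) <- paste0("f", 1:4)
  m <- pixelMap(a, 2, 2)

  # target equal to the map's own pixel distances gives zero cost
  own <- distanceMatrix(as.matrix(dist(a / 2)), labels = rownames(a))
  expect_equal(mapCost(m, own), 0)

  # hand evaluation of the 6 absolute terms for a printed target
  delta <- matrix(0.3, 4, 4); diag(delta) <- 0
  deltaM <- distanceMatrix(delta, labels = rownames(a))
  pd <- as.matrix(dist(a / 2))
  handCost <- sum(abs(pd[upper.tri(pd)] - 0.3))
  expect_equal(mapCost(m, deltaM), handCost, tolerance = 1e-12)

  # swapping two features with identical target rows leaves cost unchanged
  a2 <- a; a2[c(1, 2), ] <- a[c(2, 1), ]
  expect_equal(mapCost(pixelMap(a2, 2, 2), deltaM), mapCost(m, deltaM))

  expect_error(mapCost(m, equilateral(0.5)), "mismatch")
})

test_that("hill climbing strictly decreases cost and stops at 1-swap local optima", {
  set.seed(12)
  for (trial in 1:4) {
    p <- sample(5:9, 1)
    ft <- makeTable(12, p, seed = trial + 30)
    d <- featureDistanceMatrix(ft)
    d <- distanceMatrix(d@.Data / max(d@.Data), labels = featureNames(d))
    m0 <- randomMap(featureNames(ft), seed = trial)
    hc <- hillClimb(m0, d)
    expect_lte(hc$report@finalCost, hc$report@initialCost)
    if (length(hc$report@costTrace) > 1)
      expect_true(all(diff(hc$report@costTrace) < 0))
    # exhaustive 1-swap neighbourhood enumeration
    expect_true(isOneSwapOptimal(hc$map, d))
    # a second climb from the optimum is a fixed point
    hc2 <- hillClimb(hc$map, d)
    expect_identical(assignment(hc2$map), assignment(hc$map))
    expect_equal(hc2$report@nSweeps, 1L)
    expect_length(hc2$report@costTrace, 0)
  }
})

test_that("exactly realizable targets are recognised as zero-cost fixed points", {
  a <- cbind(row = c(0L, 0L, 1L, 2L), col = c(0L, 2L, 1L, 2L))
  rownames(a) <- paste0("f", 1:4)
  m <- pixelMap(a, 3, 3)
  target <- distanceMatrix(as.matrix(dist(a / 3)), labels = rownames(a))
  hc <- hillClimb(m, target)
  expect_equal(hc$report@finalCost, 0)
  expect_identical(assignment(hc$map), a)
})

test_that("the end-to-end map pipeline is deterministic and improves on its start", {
  ft <- normalizeFeatures(makeTable(25, 16, seed = 44))
  cfg <- bmdsConfig(nIter = 300, burnIn = 150, seed = 17)
  r1 <- buildRefinedMap(ft, bmds = cfg)
  r2 <- buildRefinedMap(ft, bmds = cfg)
  expect_identical(assignment(pixelMapOf(r1)), assignment(pixelMapOf(r2)))
  expect_equal(gridDim(pixelMapOf(r1)), c(rows = 4L, cols = 4L))
  rep1 <- hillClimbReport(r1)
  expect_lte(rep1@finalCost, rep1@initialCost)
  expect_equal(rep1@finalCost, mapCost(pixelMapOf(r1), r1@delta),
               tolerance = 1e-9)

  # ablation modes run and stay valid
  rAbl <- buildRefinedMap(ft, init = "random", useBmds = FALSE, seed = 3)
  expect_s4_class(pixelMapOf(rAbl), "PixelMap")
  rLe <- buildRefinedMap(ft, init = "le", useBmds = FALSE, kNeighbors = 6)
  expect_s4_class(pixelMapOf(rLe), "PixelMap")
})

test_that("pixel maps serialize with their JSON header", {
  m <- randomMap(paste0("f", 1:10), seed = 5)
  tf <- tempfile(fileext = ".csv")
  writePixelMap(m, tf, meta = list(method = "random", seed = 5))
  back <- readPixelMap(tf)
  expect_identical(assignment(back), assignment(m))
  expect_identical(gridDim(back), gridDim(m))
  hdr <- jsonlite::read_json(paste0(tf, ".json"))
  expect_equal(hdr$method, "random")
  expect_equal(hdr$seed, 5)
})
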