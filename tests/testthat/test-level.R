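test_that("omega transforms follow their definitions, with a log floor", {
  expect_equal(transformOmega(2, "abs_im"), 2)
  expect_equal(transformOmega(3, "abs_im_squared"), 9)
  expect_equal(transformOmega(100, "log10_abs_im"), 2)
  expect_equal(transformOmega(0, "log10_abs_im"), -12)
  expect_error(transformOmega(-1, "abs_im"), "nonnegative")
})

test_that("two planted frequency groups are found by the silhouette sweep", {
  set.seed(10)
  nw <- 40
  imAbs <- cbind(0.05 * (1 + runif(nw, -0.01, 0.01)),
                 5.0 * (1 + runif(nw, -0.01, 0.01)))
  fits <- fakeFits(imAbs)
  cfg <- LevelConfig(1L, window = 8L, rank = 2L, nBands = 2:6)
  cl <- clusterLevel(fits, cfg, seed = 0L)
  expect_equal(cl$nBands, 1L)              # two clusters: band 0 and band 1
  expect_lt(abs(cl$centroidImOmega[1] - 0.05) / 0.05, 0.02)
  expect_lt(abs(cl$centroidImOmega[2] - 5.0) / 5.0, 0.02)
  expect_true(all(cl$labels[, 1] == 0L))
  expect_true(all(cl$labels[, 2] == 1L))
})

test_that("identical eigenvalues collapse to a single band with a warning", {
  fits <- fakeFits(matrix(1.0, 5, 3))
  cfg <- LevelConfig(1L, window = 8L, rank = 3L, nBands = 2:4)
  expect_warning(cl <- clusterLevel(fits, cfg, seed = 0L), "single band")
  expect_equal(cl$nBands, 0L)
  expect_true(all(cl$labels == 0L))
})

test_that("log-frequency clustering resolves decade-spaced groups that the
           linear transform cannot", {
  set.seed(11)
  groups <- c(0.01, 0.1, 10)
  vals <- as.vector(vapply(groups, function(g)
    g * exp(rnorm(40, sd = 0.05)), numeric(40)))
  logVals <- transformOmega(vals, "log10_abs_im")
  # brute-force silhouette oracle agrees with the package selection
  expect_equal(selectKSilhouette(logVals, 2:5, seed = 1L)$k,
               bruteBestK(logVals, 2:5, seed = 1L))
  expect_equal(selectKSilhouette(logVals, 2:5, seed = 1L)$k, 3L)
  km <- suppressWarnings(kmeans(logVals, 3, nstart = 20))
  ctr <- sort(10^km$centers[, 1])
  expect_lt(max(abs(ctr - groups) / groups), 0.1)
  # linear transform: the decade-spanning spread of the top group degrades
  # the sweep or the recovered centroids
  linK <- selectKSilhouette(vals, 2:5, seed = 1L)$k
  if (linK == 3L) {
    kmLin <- suppressWarnings(kmeans(vals, 3, nstart = 20))
    expect_gt(max(abs(sort(kmLin$centers[, 1]) - groups) / groups), 0.1)
  } else {
    expect_false(linK == 3L)
  }
})

test_that("window blending is exact for single and duplicated windows", {
  y <- matrix(rnorm(3 * 8), 3, 8)
  sl <- cbind(start = 1L, end = 8L)
  expect_equal(blendWindows(list(y), sl, 8L), y)
  # two fully overlapping windows with identical content
  sl2 <- cbind(start = c(1L, 1L), end = c(8L, 8L))
  expect_equal(blendWindows(list(y, y), sl2, 8L, shape = "gaussian"), y)
})

test_that("half-overlapping windows blend by the raised-cosine formula", {
  w <- 8L
  y0 <- matrix(0, 1, w); y1 <- matrix(1, 1, w)
  sl <- cbind(start = c(1L, 5L), end = c(8L, 12L))
  out <- blendWindows(list(y0, y1), sl, 12L)
  g <- pmax(sin(pi * (1:8 - 0.5) / 8)^2, 1e-3)
  for (t in c(5L, 6L, 8L)) {
    expected <- g[t - 4L] / (g[t] + g[t - 4L])
    expect_equal(out[1, t], expected, tolerance = 1e-12)
  }
  expect_error(blendWindows(list(y0), cbind(1L, 8L), 12L), "not covered")
})

test_that("band reconstructions partition the level's blended fit", {
  truth <- miniField()
  snap <- truth@composite
  lv <- fitLevel(snap, LevelConfig(1L, window = 32L, rank = 4L,
                                   nBands = 2L), seed = 3L)
  grid <- timeGrid(snap)
  full <- costsep:::reconstructBandLocalMatrix(
    lv, 0L, grid, pairsOverride = lapply(lv@fits, function(f)
      seq_along(f@omega)))
  parts <- lapply(0:lv@nBands, function(p)
    snapValues(reconstructBandLocal(lv, p, grid)))
  expect_equal(Reduce(`+`, parts), full, tolerance = 1e-10)
  # the pass-down is definitionally the band-0 reconstruction
  expect_identical(snapValues(lowpassPassdown(lv, grid)), parts[[1L]])
  expect_error(reconstructBandLocal(lv, lv@nBands + 1L, grid), "band index")
})

test_that("slow and fast planted components separate into local bands", {
  truth <- miniField()
  snap <- truth@composite
  lv <- fitLevel(snap, LevelConfig(1L, window = 32L, rank = 4L,
                                   nBands = 2L), seed = 3L)
  grid <- timeGrid(snap)
  interior <- 40:470
  fastRec <- snapValues(reconstructBandLocal(lv, lv@nBands, grid))
  fast <- truth@components[[1]]
  expect_gt(cor(as.vector(fastRec[, interior]),
                as.vector(fast[, interior])), 0.99)
  pd <- snapValues(lowpassPassdown(lv, grid))
  slow <- truth@components[[2]]
  expect_gt(cor(as.vector(pd[, interior]), as.vector(slow[, interior])),
            0.99)
})

test_that("a constant field passes down as its own background", {
  vals <- matrix(rep(c(2, -1, 0.5), 64), 3, 64)
  snap <- SnapshotMatrix(vals, TimeGrid(0, 1, 64))
  lv <- suppressWarnings(fitLevel(snap, LevelConfig(1L, window = 16L,
                                                    rank = 2L,
                                                    nBands = 1L),
                                  seed = 1L))
  pd <- snapValues(lowpassPassdown(lv, timeGrid(snap)))
  expect_equal(pd, vals, tolerance = 1e-8)
})

test_that("spatially incoherent white noise is mostly rejected by the fit", {
  set.seed(12)
  noise <- matrix(rnorm(16 * 512), 16, 512)
  snap <- SnapshotMatrix(noise, TimeGrid(0, 1, 512))
  lv <- fitLevel(snap, LevelConfig(1L, window = 64L, rank = 4L,
                                   nBands = 2L), seed = 4L)
  rec <- Reduce(`+`, lapply(0:lv@nBands, function(p)
    snapValues(reconstructBandLocal(lv, p, timeGrid(snap)))))
  expect_lt(var(as.vector(rec)) / var(as.vector(noise)), 0.2)
})

test_that("level clustering is deterministic for a fixed seed", {
  set.seed(13)
  imAbs <- cbind(runif(30, 0.01, 0.03), runif(30, 0.8, 1.2))
  fits <- fakeFits(imAbs)
  cfg <- LevelConfig(1L, window = 8L, rank = 2L, nBands = 2:5)
  a <- clusterLevel(fits, cfg, seed = 9L)
  b <- clusterLevel(fits, cfg, seed = 9L)
  expect_identical(a, b)
})
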