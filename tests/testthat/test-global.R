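makeLevelResult <- function(imAbs, labels, level = 1L, start = NULL,
                            w = 8L) {
  fits <- fakeFits(imAbs)
  if (!is.null(start))
    fits <- lapply(seq_along(fits), function(k) {
      f <- fits[[k]]
      f@start <- start[k]; f@end <- start[k] + w - 1L
      f
    })
  cent <- sort(tapply(as.vector(imAbs), as.vector(labels), mean))
  new("LevelResult",
      config = LevelConfig(level, window = w, rank = ncol(imAbs),
                           nBands = max(1L, max(labels))),
      fits = fits, labels = labels,
      centroids = as.numeric(cent), centroidImOmega = as.numeric(cent),
      nBands = max(labels))
}

test_that("nearest-neighbour interpolation selects windows as specified", {
  grid <- TimeGrid(0, 1, 40)
  imAbs <- matrix(c(0.5, 1.5), 4, 2, byrow = TRUE)
  labels <- matrix(c(0L, 1L), 4, 2, byrow = TRUE)
  lv <- makeLevelResult(imAbs, labels, start = c(1L, 9L, 17L, 25L))
  # reference times equal to the level's own mean window times: identity
  mt <- costsep:::windowMeanTimes(lv, grid)
  tab <- interpolateOmegaNN(list(lv), grid, refTimes = mt)
  expect_equal(tab$window, seq_len(4))
  expect_true(all(tab$band > 0L))
  # one source window replicated to every reference time
  lv1 <- makeLevelResult(imAbs[1, , drop = FALSE],
                         labels[1, , drop = FALSE], start = 1L)
  tab1 <- interpolateOmegaNN(list(lv1), grid, refTimes = c(0, 5, 10, 20, 30))
  expect_equal(tab1$window, rep(1L, 5))
  # equidistant reference time resolves to the earlier window
  tie <- mean(mt[1:2])
  tabTie <- interpolateOmegaNN(list(lv), grid, refTimes = tie)
  bruteNearest <- which(abs(mt - tie) == min(abs(mt - tie)))[1]
  expect_equal(unique(tabTie$window), bruteNearest)
  expect_equal(unique(tabTie$window), 1L)
})

test_that("levels without resolved fast bands are skipped with a warning", {
  grid <- TimeGrid(0, 1, 40)
  lv <- makeLevelResult(matrix(0.5, 3, 2), matrix(0L, 3, 2),
                        start = c(1L, 9L, 17L))
  expect_warning(tab <- interpolateOmegaNN(list(lv), grid, refTimes = c(5)),
                 "skipped")
  expect_equal(nrow(tab), 0L)
})

test_that("global clustering merges a leaked component across levels", {
  grid <- TimeGrid(0, 1, 400)
  set.seed(21)
  jitter1 <- function(x) x * exp(matrix(rnorm(length(x), sd = 0.02),
                                        nrow(x)))
  # level 1 resolves a fast group and a leaked mid group
  om1 <- jitter1(2 * pi / cbind(rep(10, 20), rep(100, 20)))
  lb1 <- matrix(c(2L, 1L), 20, 2, byrow = TRUE)
  lv1 <- makeLevelResult(om1, lb1, level = 1L,
                         start = seq(1L, by = 20L, length.out = 20L),
                         w = 20L)
  # level 2 resolves a slow group and the same leaked mid group
  om2 <- jitter1(2 * pi / cbind(rep(1000, 5), rep(100, 5)))
  lb2 <- matrix(c(1L, 2L), 5, 2, byrow = TRUE)
  lv2 <- makeLevelResult(om2, lb2, level = 2L,
                         start = seq(1L, by = 80L, length.out = 5L),
                         w = 80L)
  tab <- interpolateOmegaNN(list(lv1, lv2), grid)
  gb <- clusterGlobal(tab, list(lv1, lv2), k = 2:5, seed = 1L)
  expect_equal(gb@P, 3L)
  midRecords <- gb@records[abs(abs(gb@records$omegaIm) - 2 * pi / 100) <
                             0.3 * 2 * pi / 100, ]
  expect_equal(length(unique(midRecords$gband)), 1L)
  expect_setequal(unique(midRecords$level), c(1L, 2L))
  asg <- gb@assignment
  midBand <- unique(midRecords$gband)
  expect_setequal(unique(asg$level[asg$gband == midBand]), c(1L, 2L))
})

test_that("decade-spaced global groups select k = 3 against a brute-force
           silhouette oracle", {
  set.seed(20)
  groups <- c(0.001, 0.1, 10)
  vals <- as.vector(vapply(groups, function(g)
    g * exp(rnorm(30, sd = 0.1)), numeric(30)))
  logVals <- log10(vals)
  expect_equal(selectKSilhouette(logVals, 2:5, seed = 2L)$k, 3L)
  expect_equal(bruteBestK(logVals, 2:5, seed = 2L), 3L)
})

test_that("identical global frequencies give a single band", {
  grid <- TimeGrid(0, 1, 40)
  lv <- makeLevelResult(matrix(c(0.01, 1), 4, 2, byrow = TRUE),
                        matrix(c(0L, 1L), 4, 2, byrow = TRUE),
                        start = c(1L, 9L, 17L, 25L))
  tab <- interpolateOmegaNN(list(lv), grid)
  gb <- clusterGlobal(tab, list(lv), k = 2:5, seed = 1L)
  expect_equal(gb@P, 1L)
  expect_true(all(gb@records$gband == 1L))
})

test_that("global band reconstructions conserve the full fit exactly", {
  fx <- cachedModel("two_scale")
  model <- fx$model
  full <- snapValues(reconstructFull(model))
  parts <- lapply(0:nBands(model), function(p)
    snapValues(reconstructGlobalBand(model, p)))
  expect_equal(Reduce(`+`, parts), full, tolerance = 1e-12)
  # aggregation identities
  agg <- snapValues(aggregateBands(model, seq_len(nBands(model))))
  expect_equal(agg, full - parts[[1L]], tolerance = 1e-12)
  expect_equal(snapValues(aggregateBands(model, 1L)), parts[[2L]],
               tolerance = 1e-12)
  expect_error(aggregateBands(model, 0L), "background")
  expect_error(aggregateBands(model, integer(0)), "nonempty")
  expect_error(reconstructGlobalBand(model, nBands(model) + 1L),
               "valid range")
})

test_that("clustered bands are fluctuations: near-zero time mean per row", {
  fx <- cachedModel("two_scale")
  model <- fx$model
  # evaluate over whole periods of the slowest band, inside the cone of
  # influence, so the measurement itself carries no partial-cycle bias
  span <- 513:3512   # 3000 samples = 6 full periods of the 0.002 component
  for (p in seq_len(nBands(model))) {
    x <- snapValues(reconstructGlobalBand(model, p))[, span]
    meanNorm <- abs(rowMeans(x)) * sqrt(ncol(x))
    rowNorm <- sqrt(rowSums(x^2))
    keep <- rowNorm > 1e-8 * max(rowNorm)
    expect_lt(max(meanNorm[keep] / rowNorm[keep]), 0.02)
  }
})

test_that("band summary reports centroids in frequency and period", {
  fx <- cachedModel("two_scale")
  s <- suppressWarnings(bandSummary(fx$model))
  expect_equal(nrow(s), nBands(fx$model) + 1L)
  expect_false(s$wellResolved[1])
  expect_equal(s$frequency[-1], 10^s$centroidLog10ImOmega[-1] / (2 * pi))
  expect_equal(s$period[-1], 1 / s$frequency[-1])
  expect_true(all(diff(s$frequency[-1]) > 0))
  expect_equal(sum(s$varianceShare), 1, tolerance = 1e-12)
})
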