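test_that("the cone of influence flags w/2 samples at each record edge", {
  cfg <- CostsConfig(levels = list(LevelConfig(1L, 8L, rank = 2L),
                                   LevelConfig(2L, 20L, rank = 2L)))
  coi <- coiMask(cfg, 100L)
  expect_equal(which(coi@mask[1, ]), c(1:4, 97:100))
  expect_equal(which(coi@mask[2, ]), c(1:10, 91:100))
  # nesting: the larger level's mask contains the smaller's
  expect_true(all(coi@mask[1, ] <= coi@mask[2, ]))
  expect_equal(coiInterior(coi), 11:90)
  # degenerate: window as long as the record masks everything
  cfgAll <- CostsConfig(levels = list(LevelConfig(1L, 100L, rank = 2L)))
  expect_equal(sum(coiMask(cfgAll, 100L)@mask), 100L)
})

test_that("relative error behaves as a percentage of Frobenius norm", {
  x <- matrix(rnorm(40), 4, 10)
  expect_equal(relativeError(x, x), 0)
  expect_equal(relativeError(x, 0 * x), 100)
  expect_equal(relativeError(x, x / 2), 50)
  expect_error(relativeError(0 * x, x), "zero norm")
  # masking drops the excluded columns from the norm
  y <- x; y[, 1] <- 1e6
  mask <- c(TRUE, rep(FALSE, 9))
  expect_equal(relativeError(x, y, mask = mask), 0)
})

test_that("the averaged periodogram finds peaks and preserves identity", {
  m <- 2048L
  f <- 0.11
  x <- matrix(cos(2 * pi * f * (0:(m - 1))), 2, m, byrow = TRUE)
  psd <- psdCompare(x, x, segLength = 256L)
  expect_equal(psd$psdX, psd$psdXhat)
  expect_equal(psd$freq[which.max(psd$psdX)],
               psd$freq[which.min(abs(psd$freq - f))])
  # white noise is flat within 3 dB under >= 16-segment averaging
  set.seed(30)
  wn <- matrix(rnorm(4 * 2304), 4, 2304)
  flat <- psdCompare(wn, wn, segLength = 256L)
  p <- flat$psdX[2:128]
  expect_lt(max(abs(10 * log10(p / mean(p)))), 3)
})

test_that("silhouette selection matches a brute-force oracle on planted
           groups", {
  set.seed(31)
  two <- c(rnorm(40, 0, 0.05), rnorm(40, 3, 0.05))
  expect_equal(selectKSilhouette(two, 2:6, seed = 4L)$k, 2L)
  expect_equal(bruteBestK(two, 2:6, seed = 4L), 2L)
  four <- as.vector(vapply(c(0, 2, 4, 6), function(mu)
    rnorm(25, mu, 0.05), numeric(25)))
  expect_equal(selectKSilhouette(four, 2:6, seed = 4L)$k, 4L)
  expect_equal(bruteBestK(four, 2:6, seed = 4L), 4L)
  # structureless input still returns a candidate from the sweep
  unif <- seq(0, 1, length.out = 60)
  res <- suppressWarnings(selectKSilhouette(unif, 2:5, seed = 4L))
  expect_true(res$k %in% 2:5)
  expect_error(selectKSilhouette(c(1, 2, 3, 4), 5:6, seed = 1L),
               "feasible")
  expect_error(selectKSilhouette(c(1, 1, 2), 2:3, seed = 1L),
               "distinct")
})

test_that("each level's input is exactly the previous level's pass-down", {
  truth <- miniField()
  cfg <- miniConfig()
  model <- suppressWarnings(runCosts(truth@composite, cfg))
  # re-fit level by level by hand with the same seeds
  lv1 <- fitLevel(truth@composite, cfg@levels[[1L]],
                  seed = costsep:::subSeed(cfg@seed, 101L),
                  restarts = cfg@restarts)
  pd <- lowpassPassdown(lv1, timeGrid(truth@composite),
                        spaceRegistry(truth@composite))
  lv2 <- fitLevel(pd, cfg@levels[[2L]],
                  seed = costsep:::subSeed(cfg@seed, 102L),
                  restarts = cfg@restarts)
  expect_equal(model@levels[[1L]]@fits[[3L]]@omega, lv1@fits[[3L]]@omega)
  expect_equal(model@levels[[2L]]@centroidImOmega, lv2@centroidImOmega)
  expect_equal(model@levels[[2L]]@fits[[1L]]@b, lv2@fits[[1L]]@b)
})

test_that("identical configuration and seed reproduce the model bit for bit", {
  truth <- miniField()
  m1 <- suppressWarnings(runCosts(truth@composite, miniConfig(seed = 5L)))
  m2 <- suppressWarnings(runCosts(truth@composite, miniConfig(seed = 5L)))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  saveModel(m1, f1); saveModel(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a pure white-noise field is mostly excluded from the fit", {
  set.seed(32)
  noise <- SnapshotMatrix(matrix(rnorm(16 * 512), 16, 512),
                          TimeGrid(0, 1, 512))
  model <- suppressWarnings(runCosts(noise, miniConfig()))
  rec <- snapValues(reconstructFull(model))
  expect_lt(var(as.vector(rec)) / var(as.vector(snapValues(noise))), 0.2)
})

test_that("invalid windows and masked input are rejected up front", {
  truth <- miniField()
  badCfg <- CostsConfig(levels = list(LevelConfig(1L, 512L, rank = 4L)))
  expect_error(runCosts(truth@composite, badCfg), "record")
  vals <- snapValues(truth@composite)
  vals[1, 5] <- NA
  masked <- flattenToSnapshots(list(x = vals))
  expect_error(runCosts(masked, miniConfig()), "gap")
})

test_that("an amplitude-gated fast band tracks its planted envelope", {
  comps <- list(
    componentSpec(f = 0.2, pattern = "gaussian_blob",
                  patternPars = list(center = 2, width = 1.5),
                  envelope = "on_off",
                  envelopePars = list(tOn = 256L, tOff = 256L)),
    componentSpec(f = 0.01, pattern = "gaussian_blob",
                  patternPars = list(center = 6, width = 2),
                  amplitude = 1.5))
  truth <- makeMultiscaleField(comps, n = 8L, m = 1024L)
  cfg <- CostsConfig(
    levels = list(LevelConfig(1L, window = 32L, rank = 4L, nBands = 2L),
                  LevelConfig(2L, window = 160L, rank = 4L, nBands = 2L,
                              constraint = EigConstraint(
                                mode = "nonpositive"))),
    globalK = 2:4, seed = 5L)
  model <- suppressWarnings(runCosts(truth@composite, cfg))
  fast <- which.min(abs(bandCentroids(model) - 0.2))
  env <- amplitudeEnvelope(reconstructGlobalBand(model, fast), smooth = 15L)
  interior <- coiInterior(coiMask(model))
  expect_gt(cor(env[interior], truth@envelopes[[1L]][interior]), 0.9)
})
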