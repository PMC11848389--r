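# Independent oracles and shared fixtures for the suite.

# Brute-force mean silhouette width, computed from first principles
# (pairwise distances), independent of cluster::silhouette.
bruteSilhouette <- function(values, labels) {
  n <- length(values)
  d <- abs(outer(values, values, "-"))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (length(own) - 1L)
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Brute-force silhouette-optimal k over a candidate range, using the same
# k-means partitions the package would use but scoring them independently.
bruteBestK <- function(values, kRange, seed = 1L, restarts = 10L) {
  scores <- vapply(kRange, function(k) {
    km <- costsep:::kmeans1d(values, k, seed, restarts)
    bruteSilhouette(values, km$cluster)
  }, numeric(1))
  kRange[which.max(scores)]
}

# Minimal WindowFit list with prescribed |Im(omega)| values per window,
# for exercising the clustering layer without running the solver.
fakeFits <- function(imAbs) {   # matrix: windows x pairs
  lapply(seq_len(nrow(imAbs)), function(k) {
    r <- ncol(imAbs)
    costsep:::newWindowFit(k, (k - 1L) * 4L + 1L, (k - 1L) * 4L + 8L,
                           matrix(1i + 0, 2L, r),
                           complex(real = 0, imaginary = imAbs[k, ]),
                           rep(1 + 0i, r), c(0, 0), 0.01, TRUE, 1L)
  })
}

# Small two-scale field for fast end-to-end checks (distinct from the
# shipped fixtures: n = 8, m = 512, scales 0.2 and 0.01 cycles/sample).
miniField <- function() {
  comps <- list(
    componentSpec(f = 0.2, pattern = "gaussian_blob",
                  patternPars = list(center = 2, width = 1.5)),
    componentSpec(f = 0.01, pattern = "gaussian_blob",
                  patternPars = list(center = 6, width = 2),
                  amplitude = 1.5))
  makeMultiscaleField(comps, n = 8L, m = 512L)
}

miniConfig <- function(seed = 5L) {
  CostsConfig(
    levels = list(LevelConfig(1L, window = 32L, rank = 4L, nBands = 2L),
                  LevelConfig(2L, window = 160L, rank = 4L, nBands = 2L,
                              constraint = EigConstraint(
                                mode = "nonpositive"))),
    globalK = 2:4, seed = seed)
}

# Shared fitted models, computed once per test run.
.fixtureCache <- new.env(parent = emptyenv())

cachedModel <- function(name, seed = 7L) {
  key <- paste(name, seed, sep = "#")
  if (is.null(.fixtureCache[[key]])) {
    truth <- standardFixture(name)
    model <- suppressWarnings(
      runCosts(truth@composite, fixtureConfig(name, seed = seed)))
    .fixtureCache[[key]] <- list(truth = truth, model = model)
  }
  .fixtureCache[[key]]
}

# Fixture with a mid-frequency component resolvable at both levels, for
# the cross-level leakage-merge property.
cachedLeakModel <- function(seed = 7L) {
  if (is.null(.fixtureCache[["leak"]])) {
    comps <- list(
      componentSpec(f = 0.2, pattern = "gaussian_blob",
                    patternPars = list(center = 4, width = 2.5)),
      componentSpec(f = 0.02, pattern = "plane_wave",
                    patternPars = list(wavelength = 8)),
      componentSpec(f = 0.002, pattern = "localized_sine",
                    patternPars = list(center = 11, width = 5,
                                       wavelength = 10),
                    amplitude = 1.5))
    truth <- makeMultiscaleField(comps, n = 16L, m = 4096L)
    cfg <- CostsConfig(
      levels = list(LevelConfig(1L, window = 64L, rank = 6L, nBands = 3L),
                    LevelConfig(2L, window = 1024L, rank = 8L,
                                nBands = 4L,
                                constraint = EigConstraint(
                                  mode = "nonpositive"))),
      globalK = 2:6, seed = seed)
    model <- suppressWarnings(runCosts(truth@composite, cfg))
    .fixtureCache[["leak"]] <- list(truth = truth, model = model)
  }
  .fixtureCache[["leak"]]
}

relErr <- function(x, y) {
  100 * sqrt(sum((x - y)^2)) / sqrt(sum(x^2))
}
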