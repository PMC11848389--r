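# Orchestration of the full decomposition hierarchy, plus the shared
# model-selection and diagnostic utilities.

#' Pick a cluster count by silhouette score
#'
#' Runs seeded k-means for every candidate `k` and returns the candidate
#' maximizing the mean silhouette width of the partition. A best score
#' below 0.5 triggers a low-confidence warning (values without real group
#' structure reward no particular `k`).
#'
#' @param values numeric vector (>= 3 distinct values).
#' @param kRange candidate cluster counts, all in `[2, distinct - 1]`.
#' @param seed,restarts determinism controls.
#' @return list with `k` (winner), `score` (its mean silhouette) and
#'   `scores` (named vector over candidates).
#' @export
selectKSilhouette <- function(values, kRange, seed = 1L, restarts = 10L) {
  distinct <- length(unique(values))
  stopifnotMsg(distinct >= 3L, "need at least 3 distinct values")
  kRange <- as.integer(kRange[kRange >= 2L & kRange <= distinct - 1L])
  if (length(kRange) == 0L)
    stop("no feasible cluster count in [2, distinct - 1]", call. = FALSE)
  D <- stats::dist(matrix(values, ncol = 1L))
  scores <- vapply(kRange, function(k) {
    km <- kmeans1d(values, k, seed, restarts)
    mean(cluster::silhouette(km$cluster, D)[, "sil_width"])
  }, numeric(1))
  names(scores) <- kRange
  best <- which.max(scores)
  if (scores[best] < 0.5)
    warning(sprintf(
      "best silhouette %.3f < 0.5: low confidence in the band count",
      scores[best]))
  list(k = kRange[best], score = unname(scores[best]), scores = scores)
}

#' @describeIn CoiMask-class compute the mask of a configuration: per
#'   level, the first `floor(w/2)` and last `ceiling(w/2)` samples are
#'   edge-degraded.
#' @param x a [CostsConfig-class] (compute) or [CostsModel-class] (stored).
#' @param m record length in samples.
#' @param ... unused.
#' @export
setMethod("coiMask", "CostsConfig", function(x, m, ...) {
  m <- as.integer(m)
  w <- vapply(x@levels, function(l) l@window, integer(1))
  mask <- matrix(FALSE, length(w), m)
  for (i in seq_along(w)) {
    lead <- min(w[i] %/% 2L, m)
    trail <- min(as.integer(ceiling(w[i] / 2)), m)
    if (lead > 0L) mask[i, seq_len(lead)] <- TRUE
    if (trail > 0L) mask[i, (m - trail + 1L):m] <- TRUE
  }
  rownames(mask) <- paste0("level", vapply(x@levels, function(l) l@level,
                                           integer(1)))
  new("CoiMask", mask = mask, windows = w)
})

#' @describeIn CoiMask-class the stored mask of a fitted model.
#' @export
setMethod("coiMask", "CostsModel", function(x, ...) x@coi)

#' Time indices outside every level's cone of influence
#'
#' @param coi a [CoiMask-class].
#' @return integer vector of reliable (interior) time indices.
#' @export
coiInterior <- function(coi) which(colSums(coi@mask) == 0L)

#' Relative Frobenius reconstruction error, in percent
#'
#' `100 * ||x - xhat||_F / ||x||_F` over the retained entries. `mask`
#' excludes entries: a logical vector over time, a logical matrix, or a
#' [CoiMask-class] (excludes every level's edge region).
#'
#' @param x,xhat [SnapshotMatrix-class] or plain matrices of equal shape.
#' @param mask optional exclusion mask (`TRUE` = exclude).
#' @return percentage (numeric scalar).
#' @export
relativeError <- function(x, xhat, mask = NULL) {
  X <- if (is(x, "SnapshotMatrix")) snapValues(x) else as.matrix(x)
  Y <- if (is(xhat, "SnapshotMatrix")) snapValues(xhat) else as.matrix(xhat)
  stopifnotMsg(identical(dim(X), dim(Y)), "x and xhat shapes differ")
  if (is(mask, "CoiMask")) mask <- colSums(mask@mask) > 0L
  if (!is.null(mask)) {
    if (is.matrix(mask)) {
      X <- X[!mask]; Y <- Y[!mask]
    } else {
      X <- X[, !mask, drop = FALSE]; Y <- Y[, !mask, drop = FALSE]
    }
  }
  nx <- frobenius(X)
  if (nx == 0)
    stop("reference field has zero norm; relative error undefined",
         call. = FALSE)
  100 * frobenius(X - Y) / nx
}

#' Welch-averaged power spectral density comparison
#'
#' Splits each spatial row into Hann-tapered segments of `segLength`
#' samples with 50% overlap, averages the one-sided modified periodograms
#' over segments and rows, for the input and the reconstruction on a
#' common frequency grid.
#'
#' @param x,xhat [SnapshotMatrix-class] or matrices of equal shape.
#' @param segLength segment length in samples (`<= m`).
#' @param dt sample interval (taken from `x` when it is a
#'   `SnapshotMatrix`).
#' @return list with `freq`, `psdX`, `psdXhat`.
#' @export
psdCompare <- function(x, xhat, segLength, dt = NULL) {
  if (is(x, "SnapshotMatrix")) {
    if (is.null(dt)) dt <- timeGrid(x)@dt
    x <- snapValues(x)
  }
  if (is(xhat, "SnapshotMatrix")) xhat <- snapValues(xhat)
  if (is.null(dt)) dt <- 1
  stopifnotMsg(ncol(x) >= segLength, "record shorter than segment length")
  list(freq = welchFreq(segLength, dt),
       psdX = welchPsd(x, segLength, dt),
       psdXhat = welchPsd(xhat, segLength, dt))
}

welchFreq <- function(L, dt) (0:(L %/% 2L)) / (L * dt)

welchPsd <- function(mat, L, dt) {
  m <- ncol(mat)
  starts <- seq.int(1L, m - L + 1L, by = max(1L, L %/% 2L))
  h <- sin(pi * (seq_len(L) - 0.5) / L)^2
  scale <- dt / sum(h^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (i in seq_len(nrow(mat))) {
    for (s in starts) {
      seg <- mat[i, s:(s + L - 1L)] * h
      P <- Mod(fft(seg))^2 * scale
      p1 <- P[seq_len(nf)]
      if (L %% 2L == 0L) p1[2:(nf - 1L)] <- 2 * p1[2:(nf - 1L)]
      else p1[2:nf] <- 2 * p1[2:nf]
      acc <- acc + p1
    }
  }
  acc / (nrow(mat) * length(starts))
}

#' Run the full multiresolution decomposition
#'
#' Level 1 fits the raw data with the smallest window; each subsequent
#' level fits the previous level's low-frequency pass-down with its larger
#' window, removing resolved high-frequency content step by step. After
#' the largest level, the global scale separation clusters all
#' non-background eigenvalues across levels. Deterministic given the
#' configuration's seed.
#'
#' @param data a gap-free [SnapshotMatrix-class].
#' @param config a [CostsConfig-class].
#' @return a [CostsModel-class].
#' @export
runCosts <- function(data, config) {
  validObject(config)
  if (!is.null(data@mask) && any(data@mask))
    stop("input has unresolved gaps; run fillGaps() or drop rows first",
         call. = FALSE)
  m <- data@grid@m
  w <- vapply(config@levels, function(l) l@window, integer(1))
  if (any(w >= m))
    stop(sprintf("window length %d must be smaller than the record (m=%d)",
                 max(w), m), call. = FALSE)
  cur <- data
  levels <- vector("list", length(config@levels))
  for (i in seq_along(config@levels)) {
    levels[[i]] <- fitLevel(cur, config@levels[[i]],
                            seed = subSeed(config@seed, 100L + i),
                            restarts = config@restarts)
    if (i < length(config@levels))
      cur <- lowpassPassdown(levels[[i]], data@grid, data@registry,
                             shape = config@blendShape,
                             floor = config@blendFloor)
  }
  table <- interpolateOmegaNN(levels, data@grid)
  global <- if (nrow(table) > 0L) {
    clusterGlobal(table, levels, k = config@globalK,
                  seed = subSeed(config@seed, 999L),
                  restarts = config@restarts)
  } else {
    warning("no non-background bands at any level; only G_0 available")
    new("GlobalBands", records = table,
        assignment = data.frame(level = integer(0), window = integer(0),
                                pair = integer(0), gband = integer(0)),
        centroids = numeric(0), P = 0L, silhouette = NA_real_)
  }
  new("CostsModel", config = config, grid = data@grid,
      registry = data@registry, levels = levels, global = global,
      coi = coiMask(config, m), version = "costsep-1")
}

#' @describeIn CostsModel-class the per-level [LevelResult-class] list.
#' @param x a `CostsModel`.
#' @export
setMethod("levelResults", "CostsModel", function(x) x@levels)

#' @describeIn CostsModel-class the [GlobalBands-class].
#' @export
setMethod("globalBands", "CostsModel", function(x) x@global)

#' @describeIn CostsModel-class number of clustered global bands `P`.
#' @export
setMethod("nBands", "CostsModel", function(x) x@global@P)

#' @describeIn CostsModel-class global band centroids: `"frequency"`
#'   (cycles per time unit, default), `"period"`, `"imOmega"` or
#'   `"log10"`.
#' @param scale centroid scale.
#' @export
setMethod("bandCentroids", "CostsModel", function(x, scale = "frequency") {
  ct <- 10^x@global@centroids
  out <- switch(scale,
    frequency = ct / (2 * pi),
    period = 2 * pi / ct,
    imOmega = ct,
    log10 = x@global@centroids,
    stop("unknown centroid scale: ", scale))
  names(out) <- paste0("G", seq_along(out))
  out
})

#' @describeIn CostsModel-class the time grid of the fitted record.
#' @export
setMethod("timeGrid", "CostsModel", function(x) x@grid)

#' @describeIn CostsModel-class the space registry of the fitted record.
#' @export
setMethod("spaceRegistry", "CostsModel", function(x) x@registry)

setMethod("show", "CostsModel", function(object) {
  w <- vapply(object@config@levels, function(l) l@window, integer(1))
  cat(sprintf("CostsModel: %d level(s) (windows %s), %d global bands + G_0\n",
              length(object@levels), paste(w, collapse = ", "),
              object@global@P))
  if (object@global@P > 0L)
    cat("  centroid frequencies:",
        paste(signif(bandCentroids(object), 4), collapse = ", "),
        "cycles/time\n")
  cat(sprintf("  record: %d rows x %d samples, dt = %g\n",
              length(object@registry@variable), object@grid@m,
              object@grid@dt))
})
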