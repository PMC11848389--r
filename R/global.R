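# Global scale separation: frequency content leaks between decomposition
# levels, so the non-background eigenvalues of every level are interpolated
# to a common reference time grid, clustered in log-frequency, and each
# original eigenvalue pair is reindexed to its nearest global band.

#' Interpolate level eigenvalues to reference times (nearest neighbour)
#'
#' The reference times are the mean times of the smallest-window level's
#' windows. For each level and each reference time, the eigenvalues of the
#' source window whose mean time is nearest are selected (ties broken
#' toward the earlier window); only pairs in non-background local bands
#' (`p > 0`) are emitted. Each emitted record keeps its original
#' (level, window, pair) identity so reindexing can map back.
#'
#' @param levels list of fitted [LevelResult-class].
#' @param grid the record's [TimeGrid-class].
#' @param refTimes optional explicit reference times; default = mean window
#'   times of `levels[[1]]`.
#' @return data.frame with columns `level`, `window`, `pair`, `band`,
#'   `refTime`, `omegaRe`, `omegaIm`; attribute `"refTimes"`.
#' @export
interpolateOmegaNN <- function(levels, grid, refTimes = NULL) {
  stopifnotMsg(length(levels) >= 1L, "need at least one fitted level")
  if (is.null(refTimes)) refTimes <- windowMeanTimes(levels[[1L]], grid)
  stopifnotMsg(length(refTimes) >= 1L, "reference times must be nonempty")
  rows <- list()
  for (lv in levels) {
    if (lv@nBands < 1L) {
      warning(sprintf("level %d has no non-background bands; skipped",
                      lv@config@level))
      next
    }
    mt <- windowMeanTimes(lv, grid)
    for (tr in refTimes) {
      k <- nearestEarlier(mt, tr)
      pairs <- which(lv@labels[k, ] > 0L)
      if (length(pairs) == 0L) next
      om <- lv@fits[[k]]@omega[pairs]
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv@config@level, window = k, pair = pairs,
        band = lv@labels[k, pairs], refTime = tr,
        omegaRe = Re(om), omegaIm = Im(om))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = integer(0), window = integer(0), pair = integer(0),
               band = integer(0), refTime = numeric(0),
               omegaRe = numeric(0), omegaIm = numeric(0))
  rownames(out) <- NULL
  attr(out, "refTimes") <- refTimes
  out
}

windowMeanTimes <- function(level, grid) {
  vapply(level@fits, function(f)
    grid@t0 + ((f@start - 1L) + (f@end - 1L)) / 2 * grid@dt, numeric(1))
}

# index of the value in `x` nearest to `t`, earlier index on ties
nearestEarlier <- function(x, t) {
  d <- abs(x - t)
  which(d <= min(d) + 1e-12)[1L]
}

#' Cluster interpolated eigenvalues into global frequency bands
#'
#' k-means on `log10(|Im(omega)|)` of the interpolated records — bands can
#' span orders of magnitude in frequency, which the linear scale cannot
#' separate reliably — with a silhouette sweep when `k` is a range.
#' Clusters are sorted ascending and labelled `G_1..G_P` (`G_0` is reserved
#' for the largest level's low-frequency remainder and is never produced by
#' clustering). Every original (level, window, pair) in a non-background
#' local band is then reindexed to the global band whose centroid is
#' nearest its own `log10(|Im(omega)|)`.
#'
#' @param table omega table from [interpolateOmegaNN()].
#' @param levels the fitted [LevelResult-class] list (for reindexing).
#' @param k fixed global band count or sweep candidates.
#' @param seed,restarts k-means determinism controls.
#' @return a [GlobalBands-class].
#' @export
clusterGlobal <- function(table, levels, k = 2:8, seed = 1L,
                          restarts = 10L) {
  stopifnotMsg(nrow(table) > 0L, "empty omega table: nothing to cluster")
  vals <- log10(pmax(abs(table$omegaIm), 1e-12))
  cl <- clusterOmegaValues(vals, k, seed, restarts)
  table$gband <- cl$labels + 1L
  centroids <- cl$centroids

  assignment <- reindexPairs(levels, centroids)
  new("GlobalBands", records = table, assignment = assignment,
      centroids = centroids, P = as.integer(cl$k),
      silhouette = as.numeric(cl$silhouette))
}

reindexPairs <- function(levels, centroids) {
  rows <- list()
  for (lv in levels) {
    for (kk in seq_along(lv@fits)) {
      pairs <- which(lv@labels[kk, ] > 0L)
      if (length(pairs) == 0L) next
      v <- log10(pmax(abs(Im(lv@fits[[kk]]@omega[pairs])), 1e-12))
      g <- vapply(v, function(x) which.min(abs(centroids - x)), integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv@config@level, window = kk, pair = pairs, gband = g)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = integer(0), window = integer(0), pair = integer(0),
               gband = integer(0))
  rownames(out) <- NULL
  out
}

#' Reconstruct the contribution of one global band
#'
#' For `p >= 1`: per level, each window sums its modes assigned to `G_p`
#' (no backgrounds), windows are blended within the level, and the level
#' contributions are added. For `p = 0`: the largest level's band-0
#' reconstruction including the window backgrounds `c_k` — the unresolved
#' low-frequency remainder.
#'
#' @param model a fitted [CostsModel-class].
#' @param p global band index in `0..P`.
#' @return a [SnapshotMatrix-class].
#' @export
reconstructGlobalBand <- function(model, p) {
  gb <- model@global
  if (length(p) != 1L || p < 0L || p > gb@P)
    stop(sprintf("global band %s outside valid range 0..%d",
                 paste(p, collapse = ","), gb@P), call. = FALSE)
  cfg <- model@config
  if (p == 0) {
    lastLevel <- model@levels[[length(model@levels)]]
    return(reconstructBandLocal(lastLevel, 0L, model@grid, model@registry,
                                shape = cfg@blendShape,
                                floor = cfg@blendFloor))
  }
  total <- matrix(0, length(model@registry@variable), model@grid@m)
  asg <- gb@assignment
  for (li in seq_along(model@levels)) {
    lv <- model@levels[[li]]
    sel <- asg[asg$level == lv@config@level & asg$gband == p, , drop = FALSE]
    pairsOverride <- split(sel$pair, factor(sel$window,
                                            levels = seq_along(lv@fits)))
    total <- total + reconstructBandLocalMatrix(
      lv, 1L, model@grid, shape = cfg@blendShape, floor = cfg@blendFloor,
      pairsOverride = pairsOverride)
  }
  SnapshotMatrix(total, model@grid, model@registry)
}

#' Full global reconstruction
#'
#' The sum of all global band contributions `G_0..G_P`, the background
#' entering exactly once through `G_0`. An approximation of the denoised
#' input: spatially incoherent content (white noise) is not representable
#' by coherent exponential modes and is excluded.
#'
#' @param model a fitted [CostsModel-class].
#' @return a [SnapshotMatrix-class].
#' @export
reconstructFull <- function(model) {
  gb <- model@global
  total <- snapValues(reconstructGlobalBand(model, 0L))
  for (p in seq_len(gb@P))
    total <- total + snapValues(reconstructGlobalBand(model, p))
  SnapshotMatrix(total, model@grid, model@registry)
}

#' Aggregate selected global bands
#'
#' Sums the reconstructions of the selected bands (all `>= 1`); the
#' background is excluded by definition, so requesting band 0 is an error.
#'
#' @param model a fitted [CostsModel-class].
#' @param bands integer vector of global band indices, all `>= 1`.
#' @return a [SnapshotMatrix-class].
#' @export
aggregateBands <- function(model, bands) {
  stopifnotMsg(length(bands) >= 1L, "band selection must be nonempty")
  if (any(bands < 1L))
    stop("band 0 is the background remainder and cannot be aggregated",
         call. = FALSE)
  if (any(bands > model@global@P))
    stop(sprintf("bands outside valid range 1..%d: %s", model@global@P,
                 paste(bands[bands > model@global@P], collapse = ", ")),
         call. = FALSE)
  total <- 0
  for (p in unique(as.integer(bands)))
    total <- total + snapValues(reconstructGlobalBand(model, p))
  SnapshotMatrix(total, model@grid, model@registry)
}

#' Summary table of the global bands
#'
#' One row per band `G_0..G_P`: the cluster centroid as `log10|Im(omega)|`,
#' frequency (cycles per time unit) and period, the number of member pairs
#' per level, and each band's share of the reconstruction variance. `G_0`
#' carries no centroid and is flagged `wellResolved = FALSE`: it is the
#' largest level's unresolved remainder.
#'
#' @param model a fitted [CostsModel-class].
#' @param varianceShare logical; computing shares requires reconstructing
#'   every band (set `FALSE` to skip).
#' @return a data.frame.
#' @export
bandSummary <- function(model, varianceShare = TRUE) {
  gb <- model@global
  lvl <- vapply(model@levels, function(l) l@config@level, integer(1))
  counts <- matrix(0L, gb@P + 1L, length(lvl),
                   dimnames = list(NULL, paste0("level", lvl)))
  asg <- gb@assignment
  for (li in seq_along(lvl)) {
    tab <- table(factor(asg$gband[asg$level == lvl[li]],
                        levels = seq_len(gb@P)))
    counts[seq_len(gb@P) + 1L, li] <- as.integer(tab)
  }
  freq <- c(NA_real_, 10^gb@centroids / (2 * pi))
  out <- data.frame(
    band = 0:gb@P,
    centroidLog10ImOmega = c(NA_real_, gb@centroids),
    frequency = freq,
    period = 1 / freq,
    wellResolved = c(FALSE, rep(TRUE, gb@P)))
  out <- cbind(out, counts)
  rownames(out) <- NULL
  if (varianceShare) {
    v <- vapply(0:gb@P, function(p) {
      x <- snapValues(reconstructGlobalBand(model, p))
      if (p == 0) x <- x - rowMeans(x)   # compare fluctuations only
      sum(x^2)
    }, numeric(1))
    out$varianceShare <- v / max(sum(v), .Machine$double.eps)
  }
  out
}

setMethod("show", "GlobalBands", function(object) {
  cat(sprintf("GlobalBands: %d clustered bands (+ G_0 remainder), %d records\n",
              object@P, nrow(object@records)))
  cat("  centroid frequencies (cycles/time):",
      paste(signif(10^object@centroids / (2 * pi), 4), collapse = ", "), "\n")
  if (is.finite(object@silhouette))
    cat(sprintf("  silhouette of winning partition: %.3f\n",
                object@silhouette))
})
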