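# One decomposition level: slide-fit every window, cluster eigenvalues into
# local frequency bands, reconstruct bands with window-centre-weighted
# blending, and produce the low-frequency pass-down for the next level.

#' Frequency transforms for band clustering
#'
#' Maps `|Im(omega)|` onto the scale used for k-means band identification:
#' `abs_im` (identity), `abs_im_squared`, or `log10_abs_im` (log10 after
#' clamping at a floor of 1e-12, so exact zeros are representable).
#'
#' @param imAbs nonnegative numeric vector of `|Im(omega)|` values.
#' @param scheme transform name.
#' @return transformed values.
#' @export
transformOmega <- function(imAbs, scheme = c("abs_im", "abs_im_squared",
                                             "log10_abs_im")) {
  scheme <- match.arg(scheme)
  stopifnotMsg(all(imAbs >= 0), "imAbs must be nonnegative")
  switch(scheme,
    abs_im = imAbs,
    abs_im_squared = imAbs^2,
    log10_abs_im = log10(pmax(imAbs, 1e-12)))
}

inverseTransformOmega <- function(v, scheme) {
  switch(scheme,
    abs_im = v,
    abs_im_squared = sqrt(v),
    log10_abs_im = 10^v)
}

# Shared 1-D k-means band clustering with optional silhouette sweep.
# `k` is the total cluster count (length > 1 = sweep candidates). Returns
# 0-based labels sorted so cluster 0 has the smallest centroid.
clusterOmegaValues <- function(values, k, seed, restarts = 10L) {
  distinct <- length(unique(values))
  if (distinct < 2L) {
    return(list(labels = rep(0L, length(values)),
                centroids = unique(values), k = 1L, silhouette = NA_real_,
                degenerate = TRUE))
  }
  sil <- NA_real_
  if (length(k) > 1L) {
    feasible <- k[k >= 2L & k <= distinct - 1L]
    if (length(feasible) == 0L) {
      warning("no feasible cluster count in sweep; using a single band")
      return(list(labels = rep(0L, length(values)),
                  centroids = mean(values), k = 1L, silhouette = NA_real_,
                  degenerate = TRUE))
    }
    sel <- selectKSilhouette(values, feasible, seed = seed,
                             restarts = restarts)
    k <- sel$k
    sil <- sel$score
  } else {
    k <- min(k, distinct)
  }
  km <- kmeans1d(values, k, seed, restarts)
  ord <- order(km$centers[, 1])
  relabel <- integer(k); relabel[ord] <- seq_len(k) - 1L
  list(labels = relabel[km$cluster],
       centroids = unname(sort(km$centers[, 1])),
       k = k, silhouette = sil, degenerate = FALSE)
}

#' Cluster a level's eigenvalues into local frequency bands
#'
#' Pools the transformed `|Im(omega)|` values over all windows of the level
#' and runs seeded k-means (with a silhouette sweep when the configured
#' band count is a range). Clusters are sorted ascending by centroid and
#' relabeled `0..P`: band 0 always holds the slowest frequencies.
#'
#' @param fits list of [WindowFit-class] for the level.
#' @param config the level's [LevelConfig-class].
#' @param seed integer seed for k-means.
#' @param restarts k-means restarts.
#' @return list with `labels` (windows-by-rank integer matrix of band
#'   indices), `centroids` (transformed scale, ascending),
#'   `centroidImOmega`, `nBands` (non-background count `P`), `silhouette`.
#' @export
clusterLevel <- function(fits, config, seed = 1L, restarts = 10L) {
  stopifnotMsg(length(fits) > 0L, "empty level: no window fits to cluster")
  r <- config@rank
  imabs <- vapply(fits, function(f) abs(Im(f@omega)), numeric(r))
  imabs <- matrix(imabs, nrow = r)          # r x nWindows
  vals <- transformOmega(as.vector(imabs), config@transform)
  cl <- clusterOmegaValues(vals, config@nBands, seed, restarts)
  if (cl$degenerate && length(unique(vals)) == 1L)
    warning("all transformed |Im(omega)| identical at level ",
            config@level, "; single band")
  labels <- matrix(cl$labels, nrow = r)     # r x nWindows
  list(labels = t(labels),                  # windows x r
       centroids = cl$centroids,
       centroidImOmega = inverseTransformOmega(cl$centroids,
                                               config@transform),
       nBands = cl$k - 1L,
       silhouette = cl$silhouette)
}

#' Merge overlapping window series with centre-peaked weights
#'
#' Windowed fits are most robust near the window centre, so overlapping
#' reconstructions are combined as a weighted average
#' `out(t) = sum_k g_k(t) y_k(t) / sum_k g_k(t)` with a raised-cosine
#' (default) or Gaussian profile `g` peaking at the window midpoint and
#' floored so every covered sample has strictly positive weight. This
#' supplies the normalizing factor of the overlapped reconstruction.
#'
#' @param series list of `n x w` matrices, one per window.
#' @param slices integer matrix from [windowSlices()].
#' @param m full record length.
#' @param shape `"hann"` or `"gaussian"`.
#' @param floor weight floor.
#' @return `n x m` matrix.
#' @export
blendWindows <- function(series, slices, m, shape = "hann", floor = 1e-3) {
  stopifnotMsg(length(series) == nrow(slices),
               "need one series per window slice")
  n <- nrow(series[[1L]])
  num <- matrix(0, n, m)
  den <- numeric(m)
  for (k in seq_along(series)) {
    a <- slices[k, 1L]; b <- slices[k, 2L]
    w <- b - a + 1L
    g <- weightProfile(shape, w, floor)
    num[, a:b] <- num[, a:b] + sweep(series[[k]], 2L, g, "*")
    den[a:b] <- den[a:b] + g
  }
  if (any(den <= 0))
    stop("time indices not covered by any window: ",
         paste(utils::head(which(den <= 0), 5L), collapse = ", "),
         call. = FALSE)
  sweep(num, 2L, den, "/")
}

#' Reconstruct one local band's contribution
#'
#' Per window, sums `phi_j exp(omega_j tau) b_j` over the pairs labelled
#' with band `p`; the window background `c_k` is added for `p = 0` only.
#' Windows are merged with [blendWindows()]. A band empty in some window
#' contributes zeros there (plus `c_k` if `p = 0`).
#'
#' @param level a fitted-and-clustered [LevelResult-class].
#' @param p band index in `0..P`.
#' @param grid the record's [TimeGrid-class].
#' @param registry optional [SpaceRegistry-class] for the result.
#' @param shape,floor blending profile, see [blendWindows()].
#' @return a [SnapshotMatrix-class].
#' @export
reconstructBandLocal <- function(level, p, grid, registry = NULL,
                                 shape = "hann", floor = 1e-3) {
  stopifnotMsg(p >= 0L && p <= level@nBands,
               sprintf("band index %d outside 0..%d", p, level@nBands))
  vals <- reconstructBandLocalMatrix(level, p, grid, shape, floor)
  SnapshotMatrix(vals, grid, registry)
}

reconstructBandLocalMatrix <- function(level, p, grid, shape = "hann",
                                       floor = 1e-3, pairsOverride = NULL) {
  fits <- level@fits
  dt <- grid@dt
  slices <- cbind(vapply(fits, function(f) f@start, integer(1)),
                  vapply(fits, function(f) f@end, integer(1)))
  series <- vector("list", length(fits))
  for (k in seq_along(fits)) {
    f <- fits[[k]]
    w <- f@end - f@start + 1L
    tau <- (seq_len(w) - 1L) * dt
    pairs <- if (is.null(pairsOverride)) which(level@labels[k, ] == p)
             else pairsOverride[[k]]
    series[[k]] <- windowReconstruction(f, tau, pairs,
                                        addBackground = identical(p, 0L) ||
                                          (is.numeric(p) && p == 0))
  }
  blendWindows(series, slices, grid@m, shape, floor)
}

#' Low-frequency pass-down to the next decomposition level
#'
#' The band-0 reconstruction (including the window backgrounds `c_k`):
#' the unresolved slow components of level `l`, returned as the input for
#' level `l + 1` on the original time grid.
#'
#' @inheritParams reconstructBandLocal
#' @return a [SnapshotMatrix-class].
#' @export
lowpassPassdown <- function(level, grid, registry = NULL, shape = "hann",
                            floor = 1e-3) {
  reconstructBandLocal(level, 0L, grid, registry, shape, floor)
}

#' Fit one decomposition level
#'
#' Slides the level's window over the record, fitting each window with the
#' constrained variable-projection optimized DMD (warm-starting each window
#' from its converged predecessor), then clusters all eigenvalues into
#' local frequency bands.
#'
#' @param snap gap-free [SnapshotMatrix-class] input for this level.
#' @param config a [LevelConfig-class].
#' @param seed clustering seed.
#' @param restarts k-means restarts.
#' @return a [LevelResult-class].
#' @export
fitLevel <- function(snap, config, seed = 1L, restarts = 10L) {
  if (!is.null(snap@mask) && any(snap@mask))
    stop("input still has masked cells; gap-fill or drop rows before fitting",
         call. = FALSE)
  vals <- snap@values
  dt <- snap@grid@dt
  w <- config@window
  if (w >= snap@grid@m + 1L)
    stop(sprintf("window length %d exceeds record length %d", w,
                 snap@grid@m), call. = FALSE)
  slices <- windowSlices(snap@grid@m, w, config@stride)
  constraint <- resolveConstraint(config@constraint, w, dt)
  tau <- (seq_len(w) - 1L) * dt
  fits <- vector("list", nrow(slices))
  prev <- NULL
  nFail <- 0L
  for (k in seq_len(nrow(slices))) {
    a <- slices[k, 1L]; b <- slices[k, 2L]
    mr <- windowMeanRemove(vals[, a:b, drop = FALSE])
    omegaInit <- warmStartOmega(prev, mr$X0, tau, config@rank, dt)
    fit <- fitWindowOptDMD(mr$X0, tau, config@settings, constraint,
                           omegaInit, k = k, start = a, end = b, c = mr$c)
    stale <- !fit@converged ||
      (fit@residual > 0.05 &&
         fit@residual > 1.3 * max(prevResidual(prev), 1e-6))
    if (stale && !is.null(prev)) {
      # a stale warm start can strand the optimizer in a local optimum
      # (e.g. after a transient switches on); retry cold and keep the best
      coldInit <- warmStartOmega(NULL, mr$X0, tau, config@rank, dt)
      refit <- fitWindowOptDMD(mr$X0, tau, config@settings, constraint,
                               coldInit, k = k, start = a, end = b,
                               c = mr$c)
      if (refit@residual <= fit@residual) fit <- refit
    }
    if (!is.finite(fit@residual)) nFail <- nFail + 1L
    fits[[k]] <- fit
    prev <- fit
  }
  if (nFail == length(fits))
    stop(sprintf("level %d: every window failed to converge", config@level),
         call. = FALSE)
  cl <- clusterLevel(fits, config, seed = seed, restarts = restarts)
  new("LevelResult", config = config, fits = fits, labels = cl$labels,
      centroids = cl$centroids, centroidImOmega = cl$centroidImOmega,
      nBands = cl$nBands)
}

prevResidual <- function(prev) {
  if (is.null(prev) || !is.finite(prev@residual)) 0 else prev@residual
}

# An EigConstraint with rho = NA means "auto": one e-fold per window
# duration, resolvable only once w and dt are known.
resolveConstraint <- function(constraint, w, dt) {
  if (constraint@mode == "two_sided_small" && is.na(constraint@rho))
    return(EigConstraint(rho = 1 / (w * dt), mode = "two_sided_small"))
  constraint
}

#' @describeIn LevelResult-class number of non-background bands `P`.
#' @param x a `LevelResult`.
#' @export
setMethod("nBands", "LevelResult", function(x) x@nBands)

#' @describeIn LevelResult-class band centroids; `scale = "imOmega"`
#'   (default) in `|Im(omega)|` units, `"transformed"` on the clustering
#'   scale, `"frequency"` in cycles per time unit.
#' @param scale centroid scale.
#' @export
setMethod("bandCentroids", "LevelResult", function(x, scale = "imOmega") {
  ct <- switch(scale,
    imOmega = x@centroidImOmega,
    transformed = x@centroids,
    frequency = x@centroidImOmega / (2 * pi),
    stop("unknown centroid scale: ", scale))
  names(ct) <- as.character(seq_along(ct) - 1L)
  ct
})

setMethod("show", "LevelResult", function(object) {
  cat(sprintf(
    "LevelResult level %d: %d windows (w=%d, stride=%d, rank=%d), %d+1 bands\n",
    object@config@level, length(object@fits), object@config@window,
    object@config@stride, object@config@rank, object@nBands))
  cat("  band centroids |Im(omega)|:",
      paste(signif(object@centroidImOmega, 4), collapse = ", "), "\n")
  res <- vapply(object@fits, function(f) f@residual, numeric(1))
  cat(sprintf("  window residuals: median %.3g, max %.3g\n",
              stats::median(res), max(res)))
})
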