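# Canonical spatiotemporal data model: flattening multi-variable arrays to
# a single space dimension, gap handling, and window bookkeeping.

#' @describeIn SnapshotMatrix-class the raw `n x m` value matrix.
#' @param x a `SnapshotMatrix`.
#' @export
setMethod("snapValues", "SnapshotMatrix", function(x) x@values)

#' @describeIn SnapshotMatrix-class the time grid.
#' @export
setMethod("timeGrid", "SnapshotMatrix", function(x) x@grid)

#' @describeIn SnapshotMatrix-class the space registry.
#' @export
setMethod("spaceRegistry", "SnapshotMatrix", function(x) x@registry)

#' @describeIn SnapshotMatrix-class the missing-data mask (or `NULL`).
#' @export
setMethod("gapMask", "SnapshotMatrix", function(x) x@mask)

#' @describeIn SnapshotMatrix-class number of flattened spatial rows.
#' @export
setMethod("nSpace", "SnapshotMatrix", function(x) nrow(x@values))

#' @describeIn SnapshotMatrix-class number of time samples.
#' @export
setMethod("nTime", "SnapshotMatrix", function(x) ncol(x@values))

#' @describeIn TimeGrid-class the vector of sample times.
#' @param x a `TimeGrid`.
#' @export
setMethod("timepoints", "TimeGrid", function(x)
  x@t0 + (seq_len(x@m) - 1) * x@dt)

#' @describeIn SnapshotMatrix-class sample times of the grid.
#' @export
setMethod("timepoints", "SnapshotMatrix", function(x) timepoints(x@grid))

setMethod("show", "SnapshotMatrix", function(object) {
  cat(sprintf("SnapshotMatrix: %d spatial rows x %d samples (dt = %g)\n",
              nSpace(object), nTime(object), object@grid@dt))
  vars <- unique(object@registry@variable)
  cat("  variables:", paste(vars, collapse = ", "), "\n")
  if (!is.null(object@mask))
    cat(sprintf("  missing cells: %d\n", sum(object@mask)))
})

#' Flatten one or more space-time arrays into a SnapshotMatrix
#'
#' Each input array must have time as its *last* dimension and all arrays
#' must share the identical time extent. Non-time dimensions are flattened
#' row-major (last spatial index varies fastest), variables are stacked in
#' declared order, and the registry records the provenance of every row so
#' that [unflatten()] is an exact inverse.
#'
#' Optionally each variable is standardized (mean removed, divided by its
#' standard deviation) before stacking, so variables with disparate units do
#' not dominate a joint fit; the scaling is recorded in the registry's
#' `dims` attribute for inversion. Off by default.
#'
#' @param fields a named list of numeric arrays (time last), or a single
#'   array.
#' @param grid a [TimeGrid-class]; defaults to `t0 = 0, dt = 1`.
#' @param standardize logical, per-variable standardization before stacking.
#' @return a [SnapshotMatrix-class].
#' @examples
#' a <- array(rnorm(2 * 2 * 5), c(2, 2, 5))
#' snap <- flattenToSnapshots(list(u = a))
#' dim(snapValues(snap))  # 4 x 5
#' @export
flattenToSnapshots <- function(fields, grid = NULL, standardize = FALSE) {
  if (is.array(fields) || is.matrix(fields)) fields <- list(x = fields)
  stopifnotMsg(length(fields) >= 1L, "empty input: no fields to flatten")
  if (is.null(names(fields)) || any(names(fields) == ""))
    names(fields) <- paste0("var", seq_along(fields))

  m <- NULL
  blocks <- list(); vars <- character(0); coords <- list()
  dims <- list(); scale <- list()
  for (nm in names(fields)) {
    a <- fields[[nm]]
    da <- dim(a)
    if (is.null(da)) da <- length(a)
    mt <- da[length(da)]
    if (is.null(m)) m <- mt
    if (mt != m)
      stop(sprintf("variable '%s' has %d time samples, expected %d",
                   nm, mt, m), call. = FALSE)
    sdims <- da[-length(da)]
    if (length(sdims) == 0L) sdims <- 1L
    nsp <- prod(sdims)
    # row-major flattening: last spatial index varies fastest
    mat <- matrix(aperm(array(a, c(sdims, m)),
                        c(rev(seq_along(sdims)), length(sdims) + 1L)),
                  nrow = nsp, ncol = m)
    mu <- 0; sg <- 1
    if (standardize) {
      mu <- mean(mat, na.rm = TRUE)
      sg <- sd(as.vector(mat), na.rm = TRUE)
      if (!is.finite(sg) || sg == 0) sg <- 1
      mat <- (mat - mu) / sg
    }
    idx <- arrayInd(seq_len(nsp),
                    .dim = rev(sdims))[, rev(seq_along(sdims)), drop = FALSE]
    blocks[[nm]] <- mat
    vars <- c(vars, rep(nm, nsp))
    coords <- c(coords, lapply(seq_len(nsp), function(i) as.integer(idx[i, ])))
    dims[[nm]] <- as.integer(sdims)
    scale[[nm]] <- c(mean = mu, sd = sg)
  }
  values <- do.call(rbind, blocks)
  rownames(values) <- NULL
  if (is.null(grid)) grid <- TimeGrid(0, 1, m)
  stopifnotMsg(grid@m == m, "grid length does not match the time axis")
  dims <- structure(dims, scale = scale)
  mask <- if (any(!is.finite(values))) !is.finite(values) else NULL
  if (!is.null(mask)) values[mask] <- 0
  SnapshotMatrix(values, grid,
                 new("SpaceRegistry", variable = vars, coord = coords,
                     dims = dims),
                 mask = mask)
}

#' @describeIn SnapshotMatrix-class invert the flattening: a named list of
#'   arrays (time last), exactly reproducing the inputs of
#'   [flattenToSnapshots()] (standardization inverted).
#' @export
setMethod("unflatten", "SnapshotMatrix", function(x) {
  reg <- x@registry
  scale <- attr(reg@dims, "scale")
  out <- list()
  for (nm in names(reg@dims)) {
    rows <- which(reg@variable == nm)
    sdims <- reg@dims[[nm]]
    mat <- x@values[rows, , drop = FALSE]
    if (!is.null(scale) && !is.null(scale[[nm]]))
      mat <- mat * scale[[nm]][["sd"]] + scale[[nm]][["mean"]]
    # rows are row-major; scatter back into a column-major array
    a <- array(0, c(sdims, nTime(x)))
    for (i in seq_along(rows)) {
      co <- reg@coord[[rows[i]]]
      idx <- cbind(matrix(co, nrow = nTime(x), ncol = length(co),
                          byrow = TRUE), seq_len(nTime(x)))
      a[idx] <- mat[i, ]
    }
    out[[nm]] <- a
  }
  out
})

#' Fill short gaps by linear interpolation in time
#'
#' Runs of masked values of duration at most `maxGap` (per row) are replaced
#' by linear interpolation between the bracketing valid samples. Longer runs
#' and runs touching the record edges remain flagged. Rows that are entirely
#' missing are reported via a warning and left flagged; the caller decides
#' whether to drop them. Non-missing values are never altered.
#'
#' @param snap a [SnapshotMatrix-class] with a mask.
#' @param maxGap maximum gap duration to fill, in time units (`>= 0`).
#' @return a `SnapshotMatrix` with filled values and an updated mask
#'   (`NULL` when nothing remains missing).
#' @export
fillGaps <- function(snap, maxGap) {
  stopifnotMsg(maxGap >= 0, "maxGap must be >= 0 time units")
  mask <- snap@mask
  if (is.null(mask)) return(snap)
  dt <- snap@grid@dt
  maxRun <- floor(maxGap / dt + 1e-9)
  vals <- snap@values
  m <- ncol(vals)
  allMissing <- integer(0)
  for (i in seq_len(nrow(vals))) {
    mi <- mask[i, ]
    if (!any(mi)) next
    if (all(mi)) { allMissing <- c(allMissing, i); next }
    r <- rle(mi)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      a <- starts[g]; b <- ends[g]
      if (a == 1L || b == m) next            # edge run: not bracketed
      if (r$lengths[g] > maxRun) next        # too long
      x0 <- vals[i, a - 1L]; x1 <- vals[i, b + 1L]
      k <- seq_len(b - a + 1L)
      vals[i, a:b] <- x0 + (x1 - x0) * k / (b - a + 2L)
      mask[i, a:b] <- FALSE
    }
  }
  if (length(allMissing))
    warning(sprintf("%d row(s) entirely missing, left flagged: %s",
                    length(allMissing),
                    paste(utils::head(allMissing, 5L), collapse = ", ")))
  if (!any(mask)) mask <- NULL
  new("SnapshotMatrix", values = vals, grid = snap@grid,
      registry = snap@registry, mask = mask)
}

#' Sliding-window index bookkeeping
#'
#' Produces the ordered window index ranges for a record of `m` samples,
#' window length `w` and hop `stride`: 1-based inclusive `[start, end]`
#' pairs starting at 1, 1 + stride, ... The final window is shifted left if
#' necessary so that its end equals `m` — every sample is covered and every
#' window has full length `w` (the exponential fit assumes `w` samples).
#'
#' @param m record length in samples.
#' @param w window length, `2 <= w <= m`.
#' @param stride hop in samples, `>= 1`.
#' @return integer matrix with columns `start`, `end`, one row per window.
#' @examples
#' windowSlices(10, 4, 3)  # rows (1,4), (4,7), (7,10)
#' @export
windowSlices <- function(m, w, stride) {
  m <- as.integer(m); w <- as.integer(w); stride <- as.integer(stride)
  if (w > m)
    stop(sprintf("window length w=%d exceeds record length m=%d", w, m),
         call. = FALSE)
  stopifnotMsg(w >= 2L, "window length must be >= 2")
  stopifnotMsg(stride >= 1L, "stride must be >= 1")
  stopifnotMsg(stride <= w,
               "stride must not exceed the window length (uncovered gaps)")
  starts <- seq.int(1L, by = stride, length.out = max(1L, (m - w) %/% stride + 1L))
  if (starts[length(starts)] + w - 1L < m) starts <- c(starts, m - w + 1L)
  cbind(start = starts, end = starts + w - 1L)
}
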