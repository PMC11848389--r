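setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Uniform time grid
#'
#' Describes the sampling of the time axis: start time `t0`, strictly
#' positive sample interval `dt` and number of samples `m`. Sample `i`
#' (1-based) sits at `t0 + (i - 1) * dt`; no missing ticks are allowed.
#'
#' @slot t0 numeric(1), time of the first sample (arbitrary units).
#' @slot dt numeric(1), sample interval in the same units, `> 0`.
#' @slot m integer(1), number of samples, `>= 2`.
#' @export
setClass("TimeGrid", representation(t0 = "numeric", dt = "numeric",
                                    m = "integer"))

setValidity("TimeGrid", function(object) {
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    return("dt must be a single finite positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    return("t0 must be a single finite number")
  if (length(object@m) != 1L || object@m < 2L)
    return("m must be a single integer >= 2")
  TRUE
})

#' @param t0,dt,m see slots.
#' @rdname TimeGrid-class
#' @export
TimeGrid <- function(t0 = 0, dt = 1, m) {
  new("TimeGrid", t0 = as.numeric(t0), dt = as.numeric(dt),
      m = as.integer(m))
}

#' Registry of flattened spatial rows
#'
#' Bookkeeping that makes the space flattening invertible. Each row of a
#' [SnapshotMatrix-class] corresponds to one record: the originating
#' variable name and its coordinate tuple in that variable's original
#' (non-time) array. `dims` keeps each variable's original non-time extents
#' so `unflatten()` can restore array shape.
#'
#' @slot variable character, one variable name per flattened row.
#' @slot coord list of integer vectors, original (1-based) coordinates.
#' @slot dims named list of integer vectors, non-time dims per variable.
#' @export
setClass("SpaceRegistry", representation(variable = "character",
                                         coord = "list",
                                         dims = "list"))

setValidity("SpaceRegistry", function(object) {
  n <- length(object@variable)
  if (n < 1L) return("registry must have at least one row")
  if (length(object@coord) != n)
    return("variable and coord must have equal length")
  key <- paste(object@variable,
               vapply(object@coord, paste, "", collapse = ","))
  if (anyDuplicated(key)) return("registry rows must be unique")
  TRUE
})

#' Flattened space-by-time snapshot matrix
#'
#' The canonical input container: a real matrix whose rows are flattened
#' spatial points (possibly stacked over several physical variables) and
#' whose columns are snapshots on a uniform [TimeGrid-class]. An optional
#' logical `mask` flags missing cells; masked data must be gap-filled (or
#' rows dropped) before any decomposition is fit.
#'
#' @slot values real matrix, `n x m` (space by time).
#' @slot grid a [TimeGrid-class] with `m` samples.
#' @slot registry a [SpaceRegistry-class] with `n` rows.
#' @slot mask optional logical matrix, `TRUE` where a value is missing.
#' @export
setClass("SnapshotMatrix", representation(values = "matrix",
                                          grid = "TimeGrid",
                                          registry = "SpaceRegistry",
                                          mask = "matrixOrNULL"))

setValidity("SnapshotMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a real matrix")
  if (nrow(v) != length(object@registry@variable))
    return(sprintf("registry has %d rows but values has %d",
                   length(object@registry@variable), nrow(v)))
  if (ncol(v) != object@grid@m)
    return(sprintf("grid declares m=%d but values has %d columns",
                   object@grid@m, ncol(v)))
  if (!is.null(object@mask)) {
    if (!identical(dim(object@mask), dim(v)))
      return("mask must have the same shape as values")
    if (any(!is.finite(v[!object@mask])))
      return("unmasked values must be finite")
  } else if (any(!is.finite(v))) {
    return("values must be finite (flag gaps via mask)")
  }
  TRUE
})

#' @param values,grid,registry,mask see slots; `registry = NULL` builds a
#'   single-variable registry named `"x"` with 1-D coordinates.
#' @rdname SnapshotMatrix-class
#' @export
SnapshotMatrix <- function(values, grid, registry = NULL, mask = NULL) {
  values <- as.matrix(values)
  if (is.null(registry)) {
    registry <- new("SpaceRegistry",
                    variable = rep("x", nrow(values)),
                    coord = lapply(seq_len(nrow(values)), function(i) i),
                    dims = list(x = nrow(values)))
  }
  new("SnapshotMatrix", values = values, grid = grid,
      registry = registry, mask = mask)
}

#' Eigenvalue constraint for the windowed DMD fit
#'
#' Most physical systems do not support unconstrained exponential growth or
#' decay, so the real part of the continuous-time eigenvalues is restricted:
#' `two_sided_small` clamps `Re(omega)` into `[-rho, rho]` (small but not
#' exactly zero), `nonpositive` clamps into `(-Inf, 0]`, `none` leaves it
#' free. The imaginary (oscillatory) part is never modified.
#'
#' @slot rho numeric(1), bound on `|Re(omega)|` in 1/time units, `>= 0`.
#' @slot mode one of `"two_sided_small"`, `"nonpositive"`, `"none"`.
#' @export
setClass("EigConstraint", representation(rho = "numeric", mode = "character"))

setValidity("EigConstraint", function(object) {
  if (!object@mode %in% c("two_sided_small", "nonpositive", "none"))
    return("mode must be two_sided_small, nonpositive or none")
  if (length(object@rho) != 1L)
    return("rho must be a single number")
  if (is.na(object@rho)) {
    # NA = auto: one e-fold per window duration, resolved at fit time
    if (object@mode != "two_sided_small")
      return("rho = NA (auto) is only meaningful for two_sided_small")
    return(TRUE)
  }
  if (!is.finite(object@rho) || object@rho < 0)
    return("rho must be a finite nonnegative number")
  if (object@mode == "two_sided_small" && object@rho == 0)
    return("two_sided_small requires rho > 0 (small, but not exactly zero)")
  TRUE
})

#' @param rho,mode see slots.
#' @rdname EigConstraint-class
#' @export
EigConstraint <- function(rho = 0, mode = c("two_sided_small", "nonpositive",
                                            "none")) {
  mode <- match.arg(mode)
  new("EigConstraint", rho = as.numeric(rho), mode = mode)
}

#' Variable-projection solver settings
#'
#' @slot maxIterations integer(1), Levenberg-Marquardt iteration cap.
#' @slot tolerance numeric(1), relative residual-change stopping threshold.
#' @slot dampingInit numeric(1), initial LM damping.
#' @slot rank integer(1), number of eigenvalue/eigenvector pairs `r`.
#' @export
setClass("VarProSettings", representation(maxIterations = "integer",
                                          tolerance = "numeric",
                                          dampingInit = "numeric",
                                          rank = "integer"))

setValidity("VarProSettings", function(object) {
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (object@tolerance <= 0) return("tolerance must be > 0")
  if (object@dampingInit <= 0) return("dampingInit must be > 0")
  if (object@rank < 1L) return("rank must be >= 1")
  TRUE
})

#' @param maxIterations,tolerance,dampingInit,rank see slots.
#' @rdname VarProSettings-class
#' @export
VarProSettings <- function(rank, maxIterations = 100L, tolerance = 1e-6,
                           dampingInit = 1.0) {
  new("VarProSettings", maxIterations = as.integer(maxIterations),
      tolerance = as.numeric(tolerance), dampingInit = as.numeric(dampingInit),
      rank = as.integer(rank))
}

#' One window's exponential-mode fit
#'
#' The decomposition of one data window: spatial modes `phi` (unit 2-norm
#' columns), continuous-time eigenvalues `omega`, complex amplitudes `b`
#' (carrying mode magnitude and phase at the window's local time origin),
#' and the removed window time-mean `c` (the per-row background). The
#' window approximation is `phi %*% diag(b) %*% exp(omega o tau) + c`.
#'
#' @slot k integer(1), window index within its level (1-based).
#' @slot start,end integer(1), inclusive sample range in the full record.
#' @slot phi complex `n x r` matrix of spatial modes, unit-norm columns.
#' @slot omega complex length-`r` eigenvalues (1/time units).
#' @slot b complex length-`r` amplitudes.
#' @slot c numeric length-`n` window time-mean.
#' @slot residual numeric(1), relative Frobenius misfit of the fit.
#' @slot converged logical(1), whether the solver met its tolerance.
#' @slot iterations integer(1), LM iterations used.
#' @export
setClass("WindowFit", representation(k = "integer", start = "integer",
                                     end = "integer", phi = "matrix",
                                     omega = "complex", b = "complex",
                                     c = "numeric", residual = "numeric",
                                     converged = "logical",
                                     iterations = "integer"))

setValidity("WindowFit", function(object) {
  r <- length(object@omega)
  if (ncol(object@phi) != r || length(object@b) != r)
    return("phi, omega and b must agree on rank r")
  if (nrow(object@phi) != length(object@c))
    return("phi rows and background c must agree on n")
  if (object@residual < 0) return("residual must be >= 0")
  if (object@end - object@start + 1L < 2L)
    return("window must span at least 2 samples")
  TRUE
})

#' Configuration of one decomposition level
#'
#' @slot level integer(1), level index (1-based; larger index = larger window).
#' @slot window integer(1), window length in samples `w`.
#' @slot stride integer(1), hop between window starts in samples.
#' @slot rank integer(1), DMD rank `r` (`r < w`).
#' @slot transform frequency transform for local band clustering: one of
#'   `"abs_im"`, `"abs_im_squared"`, `"log10_abs_im"`.
#' @slot nBands integer vector: length 1 fixes the number of non-background
#'   bands a priori; length > 1 is the candidate sweep for silhouette
#'   selection.
#' @slot constraint an [EigConstraint-class].
#' @slot settings a [VarProSettings-class] (its rank mirrors `rank`).
#' @export
setClass("LevelConfig", representation(level = "integer", window = "integer",
                                       stride = "integer", rank = "integer",
                                       transform = "character",
                                       nBands = "integer",
                                       constraint = "EigConstraint",
                                       settings = "VarProSettings"))

setValidity("LevelConfig", function(object) {
  if (object@window <= object@rank)
    return(sprintf("window length (%d) must exceed rank (%d)",
                   object@window, object@rank))
  if (object@stride < 1L) return("stride must be >= 1")
  if (!object@transform %in% c("abs_im", "abs_im_squared", "log10_abs_im"))
    return("transform must be abs_im, abs_im_squared or log10_abs_im")
  if (length(object@nBands) < 1L || any(object@nBands < 1L))
    return("nBands must be positive")
  TRUE
})

#' @param level,window,stride,rank,transform,nBands,constraint see slots.
#' @param maxIterations,tolerance,dampingInit forwarded to
#'   [VarProSettings()].
#' @rdname LevelConfig-class
#' @export
LevelConfig <- function(level, window, rank = 8L,
                        stride = max(1L, window %/% 8L),
                        transform = "abs_im", nBands = 2:8,
                        constraint = NULL, maxIterations = 100L,
                        tolerance = 1e-6, dampingInit = 1.0) {
  window <- as.integer(window)
  if (is.null(constraint)) {
    # auto rho: one e-fold per window duration, resolved once dt is known
    constraint <- EigConstraint(rho = NA_real_, mode = "two_sided_small")
  }
  new("LevelConfig", level = as.integer(level), window = window,
      stride = as.integer(stride), rank = as.integer(rank),
      transform = transform, nBands = as.integer(nBands),
      constraint = constraint,
      settings = VarProSettings(rank = rank, maxIterations = maxIterations,
                                tolerance = tolerance,
                                dampingInit = dampingInit))
}

#' All window fits and local frequency bands of one level
#'
#' @slot config the [LevelConfig-class] that produced it.
#' @slot fits list of [WindowFit-class], in window order.
#' @slot labels integer matrix `nWindows x r`; `labels[k, j]` is the local
#'   band index (0-based; band 0 = slowest) of pair `j` in window `k`.
#' @slot centroids numeric, per-band centroid on the transformed `|Im omega|`
#'   scale, strictly increasing, names `"0" ... "P"`.
#' @slot centroidImOmega numeric, same centroids mapped back to `|Im omega|`.
#' @slot nBands integer(1), number of non-background bands `P`.
#' @export
setClass("LevelResult", representation(config = "LevelConfig",
                                       fits = "list", labels = "matrix",
                                       centroids = "numeric",
                                       centroidImOmega = "numeric",
                                       nBands = "integer"))

setValidity("LevelResult", function(object) {
  if (length(object@fits) != nrow(object@labels))
    return("labels must have one row per window fit")
  if (length(object@centroids) >= 2L && any(diff(object@centroids) <= 0))
    return("band centroids must be strictly increasing")
  TRUE
})

#' Global frequency bands across all decomposition levels
#'
#' Produced by clustering nearest-neighbour-interpolated eigenvalues from
#' every level's non-background local bands on the `log10(|Im omega|)`
#' scale. `records` holds the interpolated table; `assignment` maps every
#' original (level, window, pair) with local band > 0 to its global band
#' `G_1 ... G_P` by nearest centroid. `G_0` is not clustered: it is the
#' low-frequency remainder (band 0, including backgrounds) of the largest
#' level.
#'
#' @slot records data.frame of interpolated eigenvalues with columns
#'   `level`, `window`, `pair`, `band`, `refTime`, `omegaRe`, `omegaIm`,
#'   `gband`.
#' @slot assignment data.frame with columns `level`, `window`, `pair`,
#'   `gband` for every original non-background pair.
#' @slot centroids numeric, `log10(|Im omega|)` centroids of `G_1 ... G_P`,
#'   strictly increasing.
#' @slot P integer(1), number of clustered global bands.
#' @slot silhouette numeric(1), mean silhouette of the winning partition
#'   (NA when the band count was fixed or degenerate).
#' @export
setClass("GlobalBands", representation(records = "data.frame",
                                       assignment = "data.frame",
                                       centroids = "numeric",
                                       P = "integer",
                                       silhouette = "numeric"))

setValidity("GlobalBands", function(object) {
  if (length(object@centroids) != object@P)
    return("need one centroid per clustered band")
  if (object@P >= 2L && any(diff(object@centroids) <= 0))
    return("global centroids must be strictly increasing")
  TRUE
})

#' Cone-of-influence mask
#'
#' Windowed estimates are least reliable near the edges of the record,
#' analogous to the cone of influence of a continuous wavelet transform.
#' Per level, the first and last `w/2` samples are flagged; the mask is
#' widest at the largest level.
#'
#' @slot mask logical matrix, levels by time; `TRUE` = edge-degraded.
#' @slot windows integer, the window length of each level.
#' @export
setClass("CoiMask", representation(mask = "matrix", windows = "integer"))

setValidity("CoiMask", function(object) {
  if (nrow(object@mask) != length(object@windows))
    return("one mask row per level required")
  TRUE
})

#' Full decomposition configuration
#'
#' @slot levels list of [LevelConfig-class], window lengths strictly
#'   increasing.
#' @slot globalK integer vector: fixed global band count (length 1) or
#'   silhouette sweep candidates.
#' @slot blendShape `"hann"` or `"gaussian"` window-centre weighting.
#' @slot blendFloor numeric(1), weight floor keeping denominators positive.
#' @slot seed integer(1), master seed for all stochastic steps.
#' @slot restarts integer(1), k-means restarts.
#' @export
setClass("CostsConfig", representation(levels = "list",
                                       globalK = "integer",
                                       blendShape = "character",
                                       blendFloor = "numeric",
                                       seed = "integer",
                                       restarts = "integer"))

setValidity("CostsConfig", function(object) {
  if (length(object@levels) < 1L) return("need at least one level")
  w <- vapply(object@levels, function(l) l@window, integer(1))
  if (length(w) >= 2L && any(diff(w) <= 0))
    return("window lengths must be strictly increasing across levels")
  if (!object@blendShape %in% c("hann", "gaussian"))
    return("blendShape must be hann or gaussian")
  TRUE
})

#' @param levels,globalK,blendShape,blendFloor,seed,restarts see slots.
#' @rdname CostsConfig-class
#' @export
CostsConfig <- function(levels, globalK = 2:8, blendShape = "hann",
                        blendFloor = 1e-3, seed = 1L, restarts = 10L) {
  if (is(levels, "LevelConfig")) levels <- list(levels)
  new("CostsConfig", levels = levels, globalK = as.integer(globalK),
      blendShape = blendShape, blendFloor = as.numeric(blendFloor),
      seed = as.integer(seed), restarts = as.integer(restarts))
}

#' Fitted multiresolution scale-separation model
#'
#' @slot config the [CostsConfig-class] used.
#' @slot grid input [TimeGrid-class].
#' @slot registry input [SpaceRegistry-class].
#' @slot levels list of [LevelResult-class], one per decomposition level.
#' @slot global a [GlobalBands-class] (slot may be an empty list-placeholder
#'   before global separation).
#' @slot coi the [CoiMask-class] of this configuration.
#' @slot version archive format version string.
#' @export
setClass("CostsModel", representation(config = "CostsConfig",
                                      grid = "TimeGrid",
                                      registry = "SpaceRegistry",
                                      levels = "list",
                                      global = "GlobalBands",
                                      coi = "CoiMask",
                                      version = "character"))
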