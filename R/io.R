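# Model persistence (single-file JSON archive), band export, and the wide
# CSV snapshot format.

ARCHIVE_VERSION <- "costsep-1"

# (+ 0 normalizes IEEE negative zeros, which JSON readers collapse to 0)
cplxOut <- function(z) list(re = Re(z) + 0, im = Im(z) + 0)
cplxIn <- function(l) complex(real = unlist(l$re), imaginary = unlist(l$im))

levelConfigOut <- function(cfg) {
  list(level = cfg@level, window = cfg@window, stride = cfg@stride,
       rank = cfg@rank, transform = cfg@transform, nBands = cfg@nBands,
       constraint = list(rho = cfg@constraint@rho,
                         mode = cfg@constraint@mode),
       settings = list(maxIterations = cfg@settings@maxIterations,
                       tolerance = cfg@settings@tolerance,
                       dampingInit = cfg@settings@dampingInit))
}

levelConfigIn <- function(l) {
  LevelConfig(level = l$level, window = l$window, stride = l$stride,
              rank = l$rank, transform = l$transform,
              nBands = unlist(l$nBands),
              constraint = new("EigConstraint",
                               rho = as.numeric(l$constraint$rho %||%
                                                  NA_real_),
                               mode = l$constraint$mode),
              maxIterations = l$settings$maxIterations,
              tolerance = l$settings$tolerance,
              dampingInit = l$settings$dampingInit)
}

configOut <- function(cfg) {
  list(levels = lapply(cfg@levels, levelConfigOut), globalK = cfg@globalK,
       blendShape = cfg@blendShape, blendFloor = cfg@blendFloor,
       seed = cfg@seed, restarts = cfg@restarts)
}

configIn <- function(l) {
  CostsConfig(levels = lapply(l$levels, levelConfigIn),
              globalK = unlist(l$globalK), blendShape = l$blendShape,
              blendFloor = l$blendFloor, seed = l$seed,
              restarts = l$restarts)
}

#' Save a fitted model to a single-file archive
#'
#' Writes the complete decomposition — configuration, every window fit
#' (complex arrays split into real/imaginary parts for portability), local
#' band labels, global bands and provenance — as a versioned JSON archive
#' at full numeric precision. [loadModel()] reproduces every
#' reconstruction to better than 1e-12 relative.
#'
#' @param model a fitted [CostsModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  if (!is(model, "CostsModel"))
    stop("saveModel requires a fitted CostsModel", call. = FALSE)
  gb <- model@global
  reg <- model@registry
  payload <- list(
    format_version = ARCHIVE_VERSION,
    config = configOut(model@config),
    grid = list(t0 = model@grid@t0, dt = model@grid@dt, m = model@grid@m),
    registry = list(variable = reg@variable, coord = reg@coord,
                    dims = reg@dims,
                    scale = attr(reg@dims, "scale")),
    levels = lapply(model@levels, function(lv) list(
      config = levelConfigOut(lv@config),
      labels = lv@labels,
      centroids = lv@centroids,
      centroidImOmega = lv@centroidImOmega,
      nBands = lv@nBands,
      fits = lapply(lv@fits, function(f) list(
        k = f@k, start = f@start, end = f@end,
        phi = cplxOut(f@phi), omega = cplxOut(f@omega), b = cplxOut(f@b),
        c = f@c, residual = f@residual, converged = f@converged,
        iterations = f@iterations)))),
    global = list(records = as.list(gb@records),
                  assignment = as.list(gb@assignment),
                  centroids = gb@centroids, P = gb@P,
                  silhouette = gb@silhouette))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' Load a model archive
#'
#' Inverse of [saveModel()]; refuses archives with an unknown format
#' version and fails cleanly (no partial model) on corrupt files.
#'
#' @param path archive path.
#' @return a [CostsModel-class].
#' @export
loadModel <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyMatrix = TRUE, simplifyDataFrame = FALSE),
    error = function(e)
      stop(sprintf("cannot parse model archive '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  required <- c("format_version", "config", "grid", "registry", "levels",
                "global")
  missing <- setdiff(required, names(payload))
  if (length(missing))
    stop("model archive is missing group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!identical(payload$format_version, ARCHIVE_VERSION))
    stop(sprintf(
      "archive format version '%s' not supported (this build reads '%s')",
      payload$format_version, ARCHIVE_VERSION), call. = FALSE)

  config <- configIn(payload$config)
  grid <- TimeGrid(payload$grid$t0, payload$grid$dt, payload$grid$m)
  dims <- lapply(payload$registry$dims, function(d) as.integer(unlist(d)))
  if (!is.null(payload$registry$scale))
    attr(dims, "scale") <- lapply(payload$registry$scale, unlist)
  registry <- new("SpaceRegistry",
                  variable = unlist(payload$registry$variable),
                  coord = lapply(payload$registry$coord,
                                 function(co) as.integer(unlist(co))),
                  dims = dims)
  levels <- lapply(payload$levels, levelIn)
  gbp <- payload$global
  dfIn <- function(cols, template) {
    if (length(cols) == 0L || length(cols[[1L]]) == 0L) return(template)
    as.data.frame(lapply(cols, unlist))
  }
  recTemplate <- data.frame(level = integer(0), window = integer(0),
                            pair = integer(0), band = integer(0),
                            refTime = numeric(0), omegaRe = numeric(0),
                            omegaIm = numeric(0), gband = integer(0))
  asgTemplate <- recTemplate[c("level", "window", "pair", "gband")]
  global <- new("GlobalBands",
                records = dfIn(gbp$records, recTemplate),
                assignment = dfIn(gbp$assignment, asgTemplate),
                centroids = as.numeric(unlist(gbp$centroids)),
                P = as.integer(gbp$P),
                silhouette = as.numeric(gbp$silhouette %||% NA_real_))
  new("CostsModel", config = config, grid = grid, registry = registry,
      levels = levels, global = global,
      coi = coiMask(config, grid@m), version = payload$format_version)
}

levelIn <- function(lv) {
  cfg <- levelConfigIn(lv$config)
  fits <- lapply(lv$fits, function(f) {
    re <- as.matrix(f$phi$re); im <- as.matrix(f$phi$im)
    phi <- matrix(complex(real = re, imaginary = im), nrow = nrow(re))
    newWindowFit(f$k, f$start, f$end, phi, cplxIn(f$omega), cplxIn(f$b),
                 as.numeric(unlist(f$c)), f$residual, f$converged,
                 f$iterations)
  })
  labels <- as.matrix(lv$labels)
  storage.mode(labels) <- "integer"
  if (length(fits) == 1L && nrow(labels) != 1L) labels <- t(labels)
  new("LevelResult", config = cfg, fits = fits, labels = labels,
      centroids = as.numeric(unlist(lv$centroids)),
      centroidImOmega = as.numeric(unlist(lv$centroidImOmega)),
      nBands = as.integer(lv$nBands))
}

#' Export band reconstructions and the band summary
#'
#' Writes one wide CSV per selected global band (via
#' [writeSnapshotCSV()]) plus the [bandSummary()] table.
#'
#' @param model a fitted [CostsModel-class].
#' @param selection integer band indices (0 allowed: the remainder).
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
exportBands <- function(model, selection, dir) {
  bad <- selection[selection < 0L | selection > model@global@P]
  if (length(bad))
    stop("selection references absent band(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (p in unique(as.integer(selection))) {
    f <- file.path(dir, sprintf("band_G%d.csv", p))
    writeSnapshotCSV(reconstructGlobalBand(model, p), f)
    paths[sprintf("G%d", p)] <- f
  }
  sf <- file.path(dir, "bands.csv")
  utils::write.csv(bandSummary(model), sf, row.names = FALSE)
  paths["summary"] <- sf
  invisible(paths)
}

#' Read a snapshot matrix from wide CSV
#'
#' Wide format: first column is time (uniformly spaced), remaining columns
#' are flattened sensors/grid points, one per spatial row.
#'
#' @param path CSV path.
#' @return a [SnapshotMatrix-class].
#' @export
readSnapshotCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnotMsg(ncol(df) >= 2L, "wide CSV needs a time column plus sensors")
  t <- df[[1L]]
  dts <- diff(t)
  stopifnotMsg(length(dts) >= 1L && all(abs(dts - dts[1L]) <
                                          1e-6 * abs(dts[1L])),
               "time column must be uniformly spaced")
  vals <- unname(t(as.matrix(df[, -1L, drop = FALSE])))
  reg <- new("SpaceRegistry",
             variable = colnames(df)[-1L],
             coord = lapply(seq_len(nrow(vals)), function(i) i),
             dims = stats::setNames(as.list(rep(1L, nrow(vals))),
                                    colnames(df)[-1L]))
  SnapshotMatrix(vals, TimeGrid(t[1L], dts[1L], length(t)), reg)
}

#' Write a snapshot matrix as wide CSV
#'
#' @param snap a [SnapshotMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSnapshotCSV <- function(snap, path) {
  reg <- snap@registry
  cols <- vapply(seq_along(reg@variable), function(i) {
    co <- reg@coord[[i]]
    if (length(co) == 1L && co == i && length(unique(reg@variable)) == 1L &&
        sum(reg@variable == reg@variable[i]) == length(reg@variable))
      paste0(reg@variable[i], "_", i)
    else paste0(reg@variable[i], "_", paste(co, collapse = "_"))
  }, character(1))
  df <- data.frame(time = timepoints(snap), t(snap@values),
                   check.names = FALSE)
  names(df) <- c("time", cols)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
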