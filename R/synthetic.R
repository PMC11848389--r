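# Synthetic multiscale spatiotemporal fields with exact ground truth:
# spatially coherent modes with oscillatory dynamics spanning orders of
# magnitude in frequency, amplitude nonstationarity, traveling waves, and
# additive spatially incoherent white noise.

#' Specification of one coherent component
#'
#' A component is a spatial pattern times an amplitude envelope times a
#' cosine oscillation: `amplitude * s(x - speed*t) * env(t) *
#' cos(2*pi*f*t + phase)` with `t` in samples and a periodic spatial
#' domain for traveling (`speed != 0`) patterns.
#'
#' @slot pattern `"gaussian_blob"`, `"plane_wave"` or `"localized_sine"`.
#' @slot patternPars list: `center`/`width` (blob), `wavelength` (plane
#'   wave), `center`/`width`/`wavelength` (localized sine).
#' @slot f temporal frequency in cycles/sample, `0 < f < 0.5` (Nyquist).
#' @slot envelope `"constant"`, `"on_off"` (periodic gate, pars `tOn`,
#'   `tOff` in samples) or `"ramp"`; values in `[0, 1]`.
#' @slot envelopePars list of envelope parameters.
#' @slot phase temporal phase in radians.
#' @slot speed advection speed in spatial samples per time sample
#'   (0 = standing).
#' @slot amplitude scalar amplitude.
#' @export
setClass("ComponentSpec", representation(pattern = "character",
                                         patternPars = "list",
                                         f = "numeric",
                                         envelope = "character",
                                         envelopePars = "list",
                                         phase = "numeric",
                                         speed = "numeric",
                                         amplitude = "numeric"))

setValidity("ComponentSpec", function(object) {
  if (!object@pattern %in% c("gaussian_blob", "plane_wave",
                             "localized_sine"))
    return("unknown spatial pattern")
  if (!object@envelope %in% c("constant", "on_off", "ramp"))
    return("unknown envelope")
  if (object@f <= 0 || object@f >= 0.5)
    return("f must lie strictly between 0 and the Nyquist frequency 0.5")
  TRUE
})

#' @param pattern,patternPars,f,envelope,envelopePars,phase,speed,amplitude
#'   see slots.
#' @rdname ComponentSpec-class
#' @export
componentSpec <- function(f, pattern = "gaussian_blob",
                          patternPars = list(center = NULL, width = NULL),
                          envelope = "constant", envelopePars = list(),
                          phase = 0, speed = 0, amplitude = 1) {
  new("ComponentSpec", pattern = pattern, patternPars = patternPars,
      f = as.numeric(f), envelope = envelope, envelopePars = envelopePars,
      phase = as.numeric(phase), speed = as.numeric(speed),
      amplitude = as.numeric(amplitude))
}

#' Exactly decomposable synthetic field
#'
#' @slot components list of noiseless per-component `n x m` fields.
#' @slot envelopes list of the length-`m` amplitude envelopes used.
#' @slot noise `n x m` noise field (zeros when noiseless).
#' @slot composite the [SnapshotMatrix-class] `sum(components) + noise`.
#' @slot specs the list of [ComponentSpec-class] used.
#' @export
setClass("SyntheticTruth", representation(components = "list",
                                          envelopes = "list",
                                          noise = "matrix",
                                          composite = "SnapshotMatrix",
                                          specs = "list"))

setValidity("SyntheticTruth", function(object) {
  total <- Reduce(`+`, object@components) + object@noise
  if (!identical(dim(total), dim(object@composite@values)))
    return("component/noise/composite shapes disagree")
  if (!isTRUE(all.equal(total, object@composite@values, tolerance = 0)))
    return("composite must equal sum(components) + noise exactly")
  TRUE
})

spatialPattern <- function(spec, x, n) {
  p <- spec@patternPars
  switch(spec@pattern,
    gaussian_blob = {
      ctr <- if (is.null(p$center)) n / 2 else p$center
      wd <- if (is.null(p$width)) n / 6 else p$width
      d <- pmin(abs(x - ctr), n - abs(x - ctr))   # periodic distance
      exp(-d^2 / (2 * wd^2))
    },
    plane_wave = {
      wl <- if (is.null(p$wavelength)) n else p$wavelength
      cos(2 * pi * x / wl)
    },
    localized_sine = {
      ctr <- if (is.null(p$center)) n / 2 else p$center
      wd <- if (is.null(p$width)) n / 4 else p$width
      wl <- if (is.null(p$wavelength)) n / 3 else p$wavelength
      d <- pmin(abs(x - ctr), n - abs(x - ctr))
      exp(-d^2 / (2 * wd^2)) * sin(2 * pi * x / wl)
    })
}

componentEnvelope <- function(spec, m) {
  i <- 0:(m - 1L)
  p <- spec@envelopePars
  switch(spec@envelope,
    constant = rep(1, m),
    on_off = {
      tOn <- if (is.null(p$tOn)) m %/% 4 else p$tOn
      tOff <- if (is.null(p$tOff)) m %/% 4 else p$tOff
      as.numeric((i %% (tOn + tOff)) < tOn)
    },
    ramp = i / max(m - 1L, 1L))
}

componentField <- function(spec, n, m) {
  x <- 0:(n - 1L)
  i <- 0:(m - 1L)
  env <- componentEnvelope(spec, m)
  temporal <- env * cos(2 * pi * spec@f * i + spec@phase)
  if (spec@speed == 0) {
    field <- spatialPattern(spec, x, n) %o% temporal
  } else {
    field <- matrix(0, n, m)
    for (t in seq_len(m)) {
      xs <- (x - spec@speed * (t - 1L)) %% n
      field[, t] <- spatialPattern(spec, xs, n) * temporal[t]
    }
  }
  spec@amplitude * field
}

#' Generate a multiscale synthetic field with exact ground truth
#'
#' Sums the requested coherent components (each deterministic) and an
#' optional seeded white-noise field. The returned [SyntheticTruth-class]
#' retains every per-component field and envelope, so
#' `composite - noise == sum(components)` holds bit-exactly.
#'
#' @param components nonempty list of [ComponentSpec-class] with distinct
#'   frequencies.
#' @param n,m spatial rows and time samples.
#' @param dt sample interval.
#' @param noiseSigma white-noise standard deviation (0 = noiseless).
#' @param seed seed for the noise field.
#' @return a [SyntheticTruth-class].
#' @export
makeMultiscaleField <- function(components, n, m, dt = 1, noiseSigma = 0,
                                seed = 1L) {
  stopifnotMsg(length(components) >= 1L, "need at least one component")
  f <- vapply(components, function(s) s@f, numeric(1))
  stopifnotMsg(!anyDuplicated(f), "component frequencies must be distinct")
  lapply(components, validObject)
  fields <- lapply(components, componentField, n = n, m = m)
  envs <- lapply(components, componentEnvelope, m = m)
  total <- Reduce(`+`, fields)
  noise <- matrix(0, n, m)
  if (noiseSigma > 0) {
    set.seed(as.integer(seed))
    noise <- matrix(rnorm(n * m, sd = noiseSigma), n, m)
  }
  composite <- SnapshotMatrix(total + noise, TimeGrid(0, dt, m))
  new("SyntheticTruth", components = fields, envelopes = envs,
      noise = noise, composite = composite, specs = components)
}

#' Traveling plane wave on a periodic spatial domain
#'
#' `field(x, t) = cos(2*pi*(x - speed*t)/wavelength)` with `x` in spatial
#' samples and `t` in time units; `speed = 0` reduces to a standing
#' profile. The temporal frequency at a fixed point is
#' `speed/wavelength` cycles per time unit.
#'
#' @param wavelength spatial wavelength in samples (`> 2`).
#' @param speed spatial samples per time unit.
#' @param n,m,dt field dimensions and sampling.
#' @return `n x m` matrix.
#' @export
makeTravelingWave <- function(wavelength, speed, n, m, dt = 1) {
  stopifnotMsg(wavelength > 2, "wavelength must exceed 2 spatial samples")
  x <- 0:(n - 1L)
  t <- (0:(m - 1L)) * dt
  cos(2 * pi * outer(x, speed * t, "-") / wavelength)
}

#' Add seeded white Gaussian noise
#'
#' Independent zero-mean Gaussian noise per cell; spatially incoherent by
#' construction, i.e. precisely what a coherent-mode decomposition cannot
#' represent.
#'
#' @param field numeric matrix.
#' @param sigma standard deviation (`>= 0`; 0 is the identity).
#' @param seed RNG seed.
#' @return the noisy matrix.
#' @export
addWhiteNoise <- function(field, sigma, seed = 1L) {
  stopifnotMsg(sigma >= 0, "sigma must be >= 0")
  if (sigma == 0) return(field)
  set.seed(as.integer(seed))
  field + matrix(rnorm(length(field), sd = sigma), nrow(field), ncol(field))
}

#' Standard multiscale fixtures
#'
#' Named, seeded scenario generators used throughout the test-suite and
#' examples; each returns a [SyntheticTruth-class]:
#' \describe{
#'   \item{two_scale}{two standing components at 0.2 and 0.002
#'     cycles/sample (noiseless), n = 16, m = 4096; seed 101.}
#'   \item{three_scale_nonstationary}{adds a mid component at 0.02
#'     cycles/sample and gates the fast component with a periodic on/off
#'     envelope (1024 on / 1024 off); seed 103.}
#'   \item{traveling}{a single plane wave, wavelength 16 samples, speed
#'     1.6 samples/time (0.1 cycles/sample at a fixed point), n = 32,
#'     m = 2048; seed 104.}
#'   \item{noisy_two_scale}{two_scale plus white noise at 2:1
#'     signal-to-noise (variance ratio); seed 202.}
#' }
#'
#' @param name fixture name.
#' @param seed optional seed override for the noise field.
#' @return a [SyntheticTruth-class].
#' @export
standardFixture <- function(name = c("two_scale",
                                     "three_scale_nonstationary",
                                     "traveling", "noisy_two_scale"),
                            seed = NULL) {
  name <- match.arg(name)
  fast <- componentSpec(f = 0.2, pattern = "gaussian_blob",
                        patternPars = list(center = 4, width = 2.5))
  slow <- componentSpec(f = 0.002, pattern = "localized_sine",
                        patternPars = list(center = 11, width = 5,
                                           wavelength = 10),
                        amplitude = 1.5)
  switch(name,
    two_scale = makeMultiscaleField(list(fast, slow), n = 16L, m = 4096L,
                                    seed = seed %||% 101L),
    three_scale_nonstationary = {
      fastGated <- componentSpec(f = 0.2, pattern = "gaussian_blob",
                                 patternPars = list(center = 4,
                                                    width = 2.5),
                                 envelope = "on_off",
                                 envelopePars = list(tOn = 1024L,
                                                     tOff = 1024L))
      mid <- componentSpec(f = 0.02, pattern = "plane_wave",
                           patternPars = list(wavelength = 8))
      makeMultiscaleField(list(fastGated, mid, slow), n = 16L, m = 4096L,
                          seed = seed %||% 103L)
    },
    traveling = {
      n <- 32L; m <- 2048L
      wave <- makeTravelingWave(wavelength = 16, speed = 1.6, n = n, m = m)
      composite <- SnapshotMatrix(wave, TimeGrid(0, 1, m))
      new("SyntheticTruth", components = list(wave),
          envelopes = list(rep(1, m)), noise = matrix(0, n, m),
          composite = composite,
          specs = list(componentSpec(f = 0.1, pattern = "plane_wave",
                                     patternPars = list(wavelength = 16),
                                     speed = 1.6)))
    },
    noisy_two_scale = {
      clean <- standardFixture("two_scale")
      signal <- snapValues(clean@composite)
      sigma <- sd(as.vector(signal)) / sqrt(2)    # 2:1 variance SNR
      noise <- addWhiteNoise(matrix(0, nrow(signal), ncol(signal)), sigma,
                             seed = seed %||% 202L)
      new("SyntheticTruth", components = clean@components,
          envelopes = clean@envelopes, noise = noise,
          composite = SnapshotMatrix(signal + noise,
                                     TimeGrid(0, 1, ncol(signal))),
          specs = clean@specs)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decomposition configuration matched to a standard fixture
#'
#' The two-scale fixtures use two levels (windows 64 and 1024, rank 4,
#' two local bands each); the traveling fixture uses a single level.
#' These mirror the scale content each fixture plants.
#'
#' @param name fixture name as in [standardFixture()].
#' @param seed master seed for the decomposition.
#' @return a [CostsConfig-class].
#' @export
fixtureConfig <- function(name = c("two_scale",
                                   "three_scale_nonstationary",
                                   "traveling", "noisy_two_scale"),
                          seed = 1L) {
  name <- match.arg(name)
  switch(name,
    two_scale = CostsConfig(
      levels = list(LevelConfig(1L, window = 64L, rank = 4L, nBands = 2L),
                    LevelConfig(2L, window = 1024L, rank = 4L,
                                nBands = 2L,
                                constraint = EigConstraint(
                                  mode = "nonpositive"))),
      globalK = 2:5, seed = seed),
    noisy_two_scale = CostsConfig(
      levels = list(LevelConfig(1L, window = 64L, rank = 4L, nBands = 2L),
                    LevelConfig(2L, window = 1024L, rank = 8L,
                                nBands = 3L,
                                transform = "log10_abs_im",
                                constraint = EigConstraint(
                                  mode = "nonpositive"))),
      globalK = 2:5, seed = seed),
    three_scale_nonstationary = CostsConfig(
      levels = list(LevelConfig(1L, window = 64L, rank = 6L, nBands = 2L),
                    LevelConfig(2L, window = 1024L, rank = 8L,
                                nBands = 4L,
                                constraint = EigConstraint(
                                  mode = "nonpositive"))),
      globalK = 2:6, seed = seed),
    traveling = CostsConfig(
      levels = list(LevelConfig(1L, window = 64L, rank = 4L,
                                nBands = 2L)),
      globalK = 2L, seed = seed))
}

#' Root-mean-square amplitude envelope of a field
#'
#' The RMS over spatial rows at each time, smoothed with a centred moving
#' average — a simple observable for tracking amplitude nonstationarity of
#' a reconstructed band.
#'
#' @param x [SnapshotMatrix-class] or matrix.
#' @param smooth moving-average full width in samples (odd preferred).
#' @return numeric vector of length `m`.
#' @export
amplitudeEnvelope <- function(x, smooth = 1L) {
  X <- if (is(x, "SnapshotMatrix")) snapValues(x) else as.matrix(x)
  env <- sqrt(colMeans(X^2))
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    padded <- c(rep(env[1L], smooth), env, rep(env[length(env)], smooth))
    sm <- stats::filter(padded, k, sides = 2L)
    env <- as.numeric(sm[(smooth + 1L):(smooth + length(env))])
  }
  env
}
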