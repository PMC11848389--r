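# Internal numerical helpers shared across modules.

#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats kmeans rnorm runif fft approx cor sd var
NULL

# Complex (or real) least squares min ||A x - B||_F via SVD pseudoinverse.
# Rank is truncated at rtol * largest singular value; returns a matrix with
# as many columns as B.
clstsq <- function(A, B, rtol = 1e-12) {
  if (!is.matrix(B)) B <- matrix(B, ncol = 1L)
  s <- svd(A)
  keep <- s$d > rtol * max(s$d, .Machine$double.eps)
  if (!any(keep)) {
    return(matrix(0i, nrow = ncol(A), ncol = ncol(B)))
  }
  u <- s$u[, keep, drop = FALSE]
  v <- s$v[, keep, drop = FALSE]
  d <- s$d[keep]
  v %*% ((Conj(t(u)) %*% B) / d)
}

frobenius <- function(x) sqrt(sum(Mod(x)^2))

# Raised-cosine (Hann) window weight over w samples, floored so every
# covered sample keeps strictly positive weight.
hannWeights <- function(w, floor = 1e-3) {
  if (w == 1L) return(1)
  g <- sin(pi * (seq_len(w) - 0.5) / w)^2
  pmax(g, floor)
}

gaussWeights <- function(w, floor = 1e-3) {
  ctr <- (w + 1) / 2
  g <- exp(-0.5 * ((seq_len(w) - ctr) / (w / 4))^2)
  pmax(g, floor)
}

weightProfile <- function(shape, w, floor = 1e-3) {
  switch(shape,
    hann = hannWeights(w, floor),
    gaussian = gaussWeights(w, floor),
    stop("unknown blend weight shape: ", shape)
  )
}

# Deterministic sub-seed derivation; keeps results < 2^31.
subSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset) %% 100003L
}

stopifnotMsg <- function(cond, ...) {
  if (!cond) stop(..., call. = FALSE)
}

# Seeded 1-D k-means (Lloyd). Restarted Lloyd can abort on empty clusters
# when values are duplicate-heavy; fall back to a deterministic
# quantile-seeded start, which cannot place a centre outside the data.
kmeans1d <- function(values, k, seed, restarts = 10L) {
  set.seed(subSeed(seed, 17L + k))
  km <- tryCatch(
    suppressWarnings(kmeans(values, centers = k, nstart = restarts,
                            iter.max = 200L, algorithm = "Lloyd")),
    error = function(e) NULL)
  if (is.null(km)) {
    centers <- unique(stats::quantile(unique(values),
                                      probs = seq(0, 1, length.out = k),
                                      names = FALSE))
    km <- suppressWarnings(kmeans(values, centers = matrix(centers),
                                  iter.max = 200L, algorithm = "Lloyd"))
  }
  km
}
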