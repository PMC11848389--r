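# Variable-projection optimized DMD for a single data window.
#
# The window model is X0 ~ Phi diag(b) exp(omega tau'), i.e. each spatial
# mode phi_j evolves as a single complex exponential exp(omega_j t). For
# fixed omega the linear coefficients are the exact least-squares solution
# against the exponential time basis T(omega)_{ij} = exp(omega_j tau_i)
# (variable projection); omega itself is refined by damped
# Gauss-Newton/Levenberg-Marquardt steps on the projected residual, using
# the Kaufman approximation of the Golub-Pereyra Jacobian. Eigenvalue
# constraints are enforced by projection (clamping) after every step.

#' Remove the per-window time mean
#'
#' Each window is normalized before fitting by removing its time mean (the
#' background), which must be added back to reconstruct the window.
#'
#' @param X real `n x w` window matrix.
#' @return list with `X0` (centered matrix) and `c` (length-`n` row means).
#' @examples
#' windowMeanRemove(matrix(1:3, 1))  # X0 = (-1, 0, 1), c = 2
#' @export
windowMeanRemove <- function(X) {
  X <- as.matrix(X)
  c <- rowMeans(X)
  list(X0 = X - c, c = c)
}

#' Clamp eigenvalue real parts into the feasible set
#'
#' @param omega complex vector of continuous-time eigenvalues.
#' @param constraint an [EigConstraint-class].
#' @return complex vector with `Re` clamped; `Im` untouched.
#' @export
enforceEigConstraint <- function(omega, constraint) {
  if (is.na(constraint@rho) && constraint@mode == "two_sided_small")
    stop("auto (NA) rho must be resolved against a window before use",
         call. = FALSE)
  re <- Re(omega)
  re <- switch(constraint@mode,
    two_sided_small = pmin(pmax(re, -constraint@rho), constraint@rho),
    nonpositive = pmin(re, 0),
    none = re)
  complex(real = re, imaginary = Im(omega))
}

#' Initial eigenvalue guess for a window
#'
#' Warm start: when the previous window's fit exists, converged and has the
#' right rank, its eigenvalues are reused (consecutive windows overlap and
#' share dynamics). Otherwise a cold start computes the eigenvalues of the
#' best-fit linear one-step operator on the rank-`r` projection of the
#' window (exact-DMD style) and maps them to continuous time via
#' `log(lambda)/dt`.
#'
#' @param prev previous [WindowFit-class] or `NULL`.
#' @param X0 centered real `n x w` window.
#' @param tau local time vector of length `w` (only its spacing is used).
#' @param r rank.
#' @param dt sample interval.
#' @return complex vector of length `r`.
#' @export
warmStartOmega <- function(prev, X0, tau, r, dt) {
  if (!is.null(prev) && is(prev, "WindowFit") && prev@converged &&
      length(prev@omega) == r) {
    return(prev@omega)
  }
  coldStartOmega(X0, r, dt)
}

coldStartOmega <- function(X0, r, dt) {
  w <- ncol(X0)
  if (w < r + 1L)
    stop(sprintf("cold start needs w >= r + 1 (w=%d, r=%d)", w, r),
         call. = FALSE)
  # Delay-embed so oscillations that are low-rank in space (e.g. a standing
  # cosine, spatial rank 1) still expose their conjugate eigenvalue pair to
  # the one-step operator.
  # generous delay count also tempers the noise-induced damping bias of the
  # one-step operator's eigenvalues
  d <- max(2L, min(max(8L, as.integer(r)), w %/% 4L, w - r - 1L))
  if (d >= 2L && w - d >= r + 1L) {
    X0 <- do.call(rbind, lapply(seq_len(d), function(i)
      X0[, i:(w - d + i), drop = FALSE]))
    w <- ncol(X0)
  }
  X1 <- X0[, -w, drop = FALSE]
  X2 <- X0[, -1L, drop = FALSE]
  s <- svd(X1)
  keep <- which(s$d > 1e-10 * max(s$d, .Machine$double.eps))
  keep <- utils::head(keep, r)
  omega <- complex(0)
  if (length(keep) > 0L) {
    U <- s$u[, keep, drop = FALSE]
    V <- s$v[, keep, drop = FALSE]
    d <- s$d[keep]
    At <- crossprod(U, X2 %*% V) %*% diag(1 / d, length(d))
    lam <- eigen(At, only.values = TRUE)$values
    lam[Mod(lam) < 1e-12] <- 1e-6
    omega <- log(as.complex(lam)) / dt
  }
  if (length(omega) < r) {
    # pad rank-deficient windows with small, distinct oscillatory guesses
    npad <- r - length(omega)
    omega <- c(omega, complex(real = 0,
                              imaginary = seq_len(npad) * pi / (w * dt * 4)))
  }
  omega[order(abs(Im(omega)), Im(omega), Re(omega))]
}

# Exponential time basis T(omega): w x r with T_ij = exp(omega_j tau_i).
expBasis <- function(tau, omega) exp(outer(tau, omega))

# One linear solve of the variable projection: coefficients B (r x n) of
# Y ~ T B, plus the residual and an orthonormal basis of col(T).
varproLinear <- function(Tb, Y) {
  s <- svd(Tb)
  tol <- 1e-12 * max(s$d, .Machine$double.eps)
  keep <- s$d > tol
  U <- s$u[, keep, drop = FALSE]
  # minimum-norm solution: dropped directions get zero coefficients
  B <- s$v[, keep, drop = FALSE] %*% ((Conj(t(U)) %*% Y) / s$d[keep])
  R <- Y - Tb %*% B
  list(B = B, R = R, U = U, rankDeficient = any(!keep))
}

#' Fit the optimized DMD model to one centered window
#'
#' Minimizes the Frobenius misfit of `X0` against
#' `sum_j phi_j exp(omega_j tau) b_j` by variable projection with damped
#' Levenberg-Marquardt updates of `omega`. The eigenvalue constraint is
#' enforced by clamping after every accepted step. Mode columns are
#' normalized to unit 2-norm with magnitude and phase folded into `b`,
#' phase tie-broken so the largest-magnitude entry of each mode is
#' real-positive. For real input, eigenvalues are repaired to exact
#' conjugate-pair symmetry by averaging matched pairs.
#'
#' @param X0 centered real `n x w` window matrix.
#' @param tau local time vector (length `w`, uniform, starting at 0).
#' @param settings a [VarProSettings-class].
#' @param constraint an [EigConstraint-class].
#' @param omegaInit complex initial eigenvalues, length `rank`.
#' @param k,start,end window bookkeeping stored on the result.
#' @param c background vector stored on the result (default zeros).
#' @return a [WindowFit-class]; the accepted-residual history is attached
#'   as attribute `"residualTrace"`.
#' @export
fitWindowOptDMD <- function(X0, tau, settings, constraint, omegaInit,
                            k = 1L, start = 1L, end = ncol(X0), c = NULL) {
  X0 <- as.matrix(X0)
  n <- nrow(X0); w <- ncol(X0); r <- settings@rank
  stopifnotMsg(length(tau) == w, "tau must have one entry per column of X0")
  stopifnotMsg(length(omegaInit) == r, "omegaInit must have length rank")
  if (is.null(c)) c <- numeric(n)
  Y <- t(X0)                       # w x n
  normY <- frobenius(Y)

  if (normY == 0) {                # null signal: exact zero fit
    return(newWindowFit(k, start, end, matrix(0i, n, r), omegaInit,
                        rep(0i, r), c, 0, TRUE, 0L, trace = 0))
  }

  omega <- enforceEigConstraint(omegaInit, constraint)
  omega <- perturbIfDegenerate(omega, tau)
  lin <- varproLinear(expBasis(tau, omega), Y)
  if (lin$rankDeficient) {         # documented perturb-and-retry, once
    omega <- perturbIfDegenerate(omega, tau, force = TRUE)
    lin <- varproLinear(expBasis(tau, omega), Y)
  }
  res <- frobenius(lin$R) / normY
  trace <- res
  lambda <- settings@dampingInit
  converged <- FALSE
  it <- 0L

  while (it < settings@maxIterations) {
    it <- it + 1L
    if (!is.finite(res))
      return(failedFit(k, start, end, n, r, omega, c, trace))
    J <- varproJacobian(tau, omega, lin)
    scales <- sqrt(colSums(Mod(J)^2))
    scales[scales < 1e-12] <- 1
    # Gauss-Newton model R(omega + delta) ~ R + J delta: minimize its norm
    rhs <- c(-as.vector(lin$R), rep(0i, r))
    accepted <- FALSE
    for (inner in 1:12) {
      A <- rbind(J, diag(sqrt(lambda) * scales, r))
      delta <- as.vector(clstsq(A, rhs))
      omegaTrial <- enforceEigConstraint(omega + delta, constraint)
      linTrial <- varproLinear(expBasis(tau, omegaTrial), Y)
      resTrial <- frobenius(linTrial$R) / normY
      if (is.finite(resTrial) && resTrial <= res) {
        accepted <- TRUE
        lambda <- lambda / 3
        break
      }
      lambda <- lambda * 2
    }
    if (!accepted) break          # damping exhausted: local optimum
    dres <- res - resTrial
    omega <- omegaTrial; lin <- linTrial; res <- resTrial
    trace <- c(trace, res)
    if (res < 1e-12 || dres < settings@tolerance * max(res, 1e-15)) {
      converged <- TRUE
      break
    }
  }
  if (!converged && res < 1e-8) converged <- TRUE  # already at numerical floor

  # conjugate-symmetry repair for real input
  if (all(Im(Y) == 0)) {
    omega <- repairConjugateSymmetry(omega)
    lin <- varproLinear(expBasis(tau, omega), Y)
    res <- frobenius(lin$R) / normY
  }

  # normalize: phi unit columns, magnitude+phase in b, largest entry of
  # each phi real-positive
  B <- lin$B                       # r x n, row j = b_j * phi_j^T
  phi <- matrix(0i, n, r); b <- rep(0i, r)
  for (j in seq_len(r)) {
    v <- B[j, ]
    nv <- sqrt(sum(Mod(v)^2))
    if (nv < 1e-300) { phi[1, j] <- 1 + 0i; next }
    u <- v / nv
    imax <- which.max(Mod(u))
    ph <- exp(1i * Arg(u[imax]))
    phi[, j] <- u / ph
    b[j] <- nv * ph
  }
  ord <- order(abs(Im(omega)), Im(omega), Re(omega))
  newWindowFit(k, start, end, phi[, ord, drop = FALSE], omega[ord], b[ord],
               c, res, converged, it, trace = trace)
}

newWindowFit <- function(k, start, end, phi, omega, b, c, residual,
                         converged, iterations, trace = NULL) {
  fit <- new("WindowFit", k = as.integer(k), start = as.integer(start),
             end = as.integer(end), phi = phi, omega = omega, b = b,
             c = c, residual = as.numeric(residual),
             converged = converged, iterations = as.integer(iterations))
  attr(fit, "residualTrace") <- trace
  fit
}

failedFit <- function(k, start, end, n, r, omega, c, trace) {
  warning(sprintf("window %d: non-finite residual, fit flagged failed", k))
  newWindowFit(k, start, end, matrix(0i, n, r), omega, rep(0i, r), c,
               Inf, FALSE, 0L, trace = trace)
}

# Kaufman-approximation Jacobian of the projected residual w.r.t. omega:
# column j = -Pperp((tau * T_j) outer B[j,]) stacked as a vector.
varproJacobian <- function(tau, omega, lin) {
  Tb <- expBasis(tau, omega)
  U <- lin$U
  w <- length(tau); n <- ncol(lin$B); r <- length(omega)
  J <- matrix(0i, w * n, r)
  for (j in seq_len(r)) {
    Aj <- (tau * Tb[, j]) %o% lin$B[j, ]          # w x n
    Aj <- Aj - U %*% (Conj(t(U)) %*% Aj)          # project out col(T)
    J[, j] <- -as.vector(Aj)
  }
  J
}

# Deterministic tie-break for (near-)duplicate eigenvalues: the exponential
# basis degenerates, so spread duplicates slightly along Im.
perturbIfDegenerate <- function(omega, tau, force = FALSE) {
  scale <- max(Mod(omega), 1 / (max(tau) - min(tau) + 1))
  eps <- 1e-4 * scale
  if (!force) {
    d <- abs(outer(omega, omega, "-"))
    diag(d) <- Inf
    if (min(d) > 1e-8 * scale) return(omega)
  }
  omega + 1i * eps * seq_along(omega)
}

# Match eigenvalues into conjugate pairs and average; eigenvalues pairing
# with themselves (|Im| below tolerance) are made exactly real.
repairConjugateSymmetry <- function(omega, tol = 1e-6) {
  r <- length(omega)
  scale <- max(Mod(omega), 1e-12)
  used <- rep(FALSE, r)
  out <- omega
  for (j in seq_len(r)) {
    if (used[j]) next
    d <- Mod(omega - Conj(omega[j]))
    d[used] <- Inf
    l <- which.min(d)
    if (d[l] > tol * scale) next          # no partner within tolerance
    if (l == j) {
      out[j] <- complex(real = Re(omega[j]), imaginary = 0)
      used[j] <- TRUE
    } else {
      avg <- (omega[j] + Conj(omega[l])) / 2
      out[j] <- avg
      out[l] <- Conj(avg)
      used[j] <- TRUE; used[l] <- TRUE
    }
  }
  out
}

# Reconstruction of one fit over its own window (real part for real input):
# Phi diag(b) exp(omega tau') [+ c], optionally restricted to a pair subset.
windowReconstruction <- function(fit, tau, pairs = NULL, addBackground = FALSE) {
  if (is.null(pairs)) pairs <- seq_along(fit@omega)
  n <- nrow(fit@phi)
  out <- matrix(0, n, length(tau))
  if (length(pairs) > 0L) {
    E <- exp(outer(fit@omega[pairs], tau))            # |pairs| x w
    out <- Re(fit@phi[, pairs, drop = FALSE] %*% (fit@b[pairs] * E))
  }
  if (addBackground) out <- out + fit@c
  out
}

setMethod("show", "WindowFit", function(object) {
  cat(sprintf(
    "WindowFit k=%d [%d, %d], rank %d, residual %.3g, %s (%d iter)\n",
    object@k, object@start, object@end, length(object@omega),
    object@residual, if (object@converged) "converged" else "not converged",
    object@iterations))
  freqs <- sort(unique(round(abs(Im(object@omega)) / (2 * pi), 8)))
  cat("  |Im(omega)|/2pi:", paste(signif(freqs, 4), collapse = ", "), "\n")
})
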