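test_that("window mean removal is exact and invertible", {
  expect_equal(windowMeanRemove(matrix(c(5, 5, 5), 1)),
               list(X0 = matrix(0, 1, 3), c = 5))
  expect_equal(windowMeanRemove(matrix(1:3, 1)),
               list(X0 = matrix(c(-1, 0, 1), 1), c = 2))
  set.seed(1)
  X <- matrix(rnorm(8 * 32), 8, 32)
  mr <- windowMeanRemove(X)
  expect_equal(mr$X0 + mr$c, X, tolerance = 1e-15)
  expect_true(all(abs(rowSums(mr$X0)) < 1e-12))
})

test_that("eigenvalue constraints clamp only the real part", {
  con <- EigConstraint(rho = 0.1)
  expect_equal(enforceEigConstraint(0.3 + 2i, con), 0.1 + 2i)
  expect_equal(enforceEigConstraint(-0.05 + 2i, con), -0.05 + 2i)
  expect_equal(enforceEigConstraint(0.3 + 2i,
                                    EigConstraint(mode = "nonpositive")),
               0 + 2i)
  expect_equal(enforceEigConstraint(0.3 - 5i, EigConstraint(mode = "none")),
               0.3 - 5i)
  expect_error(EigConstraint(rho = 0, mode = "two_sided_small"),
               "not exactly zero")
})

test_that("a noiseless standing oscillation is recovered to machine level", {
  set.seed(1)
  n <- 16; w <- 200; tau <- 0:(w - 1)
  u <- rnorm(n); u <- u / sqrt(sum(u^2))
  X0 <- windowMeanRemove(u %o% cos(2 * pi * 0.05 * tau))$X0
  init <- warmStartOmega(NULL, X0, tau, 2L, 1)
  fit <- fitWindowOptDMD(X0, tau, VarProSettings(rank = 2L),
                         EigConstraint(rho = 1 / w), init)
  expect_lt(max(abs(abs(Im(fit@omega)) - 2 * pi * 0.05)), 1e-6)
  expect_lt(fit@residual, 1e-8)
  expect_true(fit@converged)
})

test_that("planted eigenvalues are recovered by generate-and-refit", {
  set.seed(2)
  n <- 16; w <- 200; tau <- 0:(w - 1)
  om <- c(-0.01 + 0.5i, -0.01 - 0.5i, -0.002 + 0.05i, -0.002 - 0.05i)
  phi <- matrix(complex(real = rnorm(n * 2), imaginary = rnorm(n * 2)), n, 2)
  phi <- cbind(phi[, 1], Conj(phi[, 1]), phi[, 2], Conj(phi[, 2]))
  phi <- sweep(phi, 2, sqrt(colSums(Mod(phi)^2)), "/")
  b <- c(1 + 0.5i, 1 - 0.5i, 2 + 0i, 2 + 0i)
  X0 <- Re(phi %*% (b * exp(outer(om, tau))))
  init <- warmStartOmega(NULL, X0, tau, 4L, 1)
  fit <- fitWindowOptDMD(X0, tau, VarProSettings(rank = 4L),
                         EigConstraint(mode = "none"), init)
  # pair planted and recovered by nearest match
  for (o in om) {
    d <- min(Mod(fit@omega - o))
    expect_lt(d / Mod(o), 1e-5)
  }
  expect_lt(fit@residual, 1e-8)
})

test_that("the null window yields zero amplitudes and zero residual", {
  fit <- fitWindowOptDMD(matrix(0, 4, 20), 0:19, VarProSettings(rank = 2L),
                         EigConstraint(rho = 0.05), c(0.1i, -0.1i))
  expect_true(all(Mod(fit@b) < 1e-10))
  expect_equal(fit@residual, 0)
})

test_that("warm starts pass through, fall back cold when unconverged", {
  set.seed(3)
  X0 <- windowMeanRemove(rnorm(4) %o% cos(0.2 * (0:99)))$X0
  tau <- 0:99
  prev <- fitWindowOptDMD(X0, tau, VarProSettings(rank = 2L),
                          EigConstraint(mode = "none"),
                          warmStartOmega(NULL, X0, tau, 2L, 1))
  expect_identical(warmStartOmega(prev, X0, tau, 2L, 1), prev@omega)
  # cold start lands within 20% of the true spectrum
  cold <- warmStartOmega(NULL, X0, tau, 2L, 1)
  expect_lt(max(abs(abs(Im(cold)) - 0.2)) / 0.2, 0.2)
  # a non-converged predecessor is ignored
  bad <- prev
  bad@converged <- FALSE
  expect_identical(warmStartOmega(bad, X0, tau, 2L, 1), cold)
  expect_error(warmStartOmega(NULL, X0[, 1:2], 0:1, 4L, 1), "w >= r")
})

test_that("real input yields conjugate-symmetric spectra and real output", {
  set.seed(4)
  n <- 8; w <- 120; tau <- 0:(w - 1)
  X <- rnorm(n) %o% cos(2 * pi * 0.07 * tau) +
    0.5 * rnorm(n) %o% sin(2 * pi * 0.013 * tau)
  X0 <- windowMeanRemove(X)$X0
  fit <- fitWindowOptDMD(X0, tau, VarProSettings(rank = 4L),
                         EigConstraint(rho = 1 / w),
                         warmStartOmega(NULL, X0, tau, 4L, 1))
  # omega closed under conjugation
  for (o in fit@omega) expect_lt(min(Mod(fit@omega - Conj(o))), 1e-6)
  # complex-mode reconstruction is real up to tolerance
  recon <- fit@phi %*% (fit@b * exp(outer(fit@omega, tau)))
  expect_lt(sqrt(sum(Im(recon)^2)), 1e-8 * sqrt(sum(Re(recon)^2)))
  # mode normalization: unit columns, dominant entry real-positive
  expect_equal(sqrt(colSums(Mod(fit@phi)^2)), rep(1, 4), tolerance = 1e-10)
  for (j in 1:4) {
    top <- fit@phi[which.max(Mod(fit@phi[, j])), j]
    expect_lt(abs(Arg(top)), 1e-8)
  }
})

test_that("accepted optimizer iterations never increase the residual", {
  set.seed(5)
  n <- 10; w <- 150; tau <- 0:(w - 1)
  X <- rnorm(n) %o% cos(2 * pi * 0.04 * tau) +
    matrix(rnorm(n * w, sd = 0.3), n, w)
  X0 <- windowMeanRemove(X)$X0
  fit <- fitWindowOptDMD(X0, tau, VarProSettings(rank = 2L),
                         EigConstraint(rho = 1 / w),
                         c(0.03i, -0.03i))
  trace <- attr(fit, "residualTrace")
  expect_gt(length(trace), 1L)
  expect_true(all(diff(trace) <= 1e-12))
})

test_that("refitting data synthesized from a fit reproduces it", {
  set.seed(6)
  n <- 12; w <- 160; tau <- 0:(w - 1)
  X <- rnorm(n) %o% cos(2 * pi * 0.06 * tau) +
    0.7 * rnorm(n) %o% cos(2 * pi * 0.15 * tau + 1) +
    matrix(rnorm(n * w, sd = 0.2), n, w)
  X0 <- windowMeanRemove(X)$X0
  first <- fitWindowOptDMD(X0, tau, VarProSettings(rank = 4L),
                           EigConstraint(rho = 1 / w),
                           warmStartOmega(NULL, X0, tau, 4L, 1))
  synth <- Re(first@phi %*% (first@b * exp(outer(first@omega, tau))))
  second <- fitWindowOptDMD(synth, tau, VarProSettings(rank = 4L),
                            EigConstraint(rho = 1 / w),
                            warmStartOmega(NULL, synth, tau, 4L, 1))
  expect_lt(second@residual, 1e-8)
  for (j in seq_along(first@omega)) {
    i <- which.min(Mod(second@omega - first@omega[j]))
    expect_lt(Mod(second@omega[i] - first@omega[j]) /
                max(Mod(first@omega[j]), 1e-8), 1e-5)
    expect_lt(Mod(Mod(second@b[i]) - Mod(first@b[j])) /
                max(Mod(first@b[j]), 1e-8), 1e-4)
  }
})

test_that("a loose two-sided bound approaches the unconstrained optimum", {
  set.seed(7)
  n <- 10; w <- 180; tau <- 0:(w - 1)
  X <- rnorm(n) %o% (exp(-0.003 * tau) * cos(2 * pi * 0.08 * tau)) +
    rnorm(n) %o% cos(2 * pi * 0.015 * tau)
  X0 <- windowMeanRemove(X)$X0
  init <- warmStartOmega(NULL, X0, tau, 4L, 1)
  free <- fitWindowOptDMD(X0, tau, VarProSettings(rank = 4L),
                          EigConstraint(mode = "none"), init)
  loose <- fitWindowOptDMD(X0, tau, VarProSettings(rank = 4L),
                           EigConstraint(rho = 10), init)
  for (o in free@omega)
    expect_lt(min(Mod(loose@omega - o)), 1e-4 * max(Mod(o), 1))
})
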