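---
title: "Multiresolution coherent spatiotemporal scale separation with costsep"
author: "costsep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiresolution coherent spatiotemporal scale separation with costsep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(costsep)
```

# The problem

Many measured fields — electrode-array potentials, gridded geophysical
observations, boundary-layer wind profiles — mix processes whose time
scales span several orders of magnitude. No single modal decomposition
resolves them: a global eigendecomposition smears nonstationary and
traveling features over many modes, and time–frequency transforms resolve
scale along only one axis. `costsep` addresses this by fitting *windowed*
low-rank exponential models at a hierarchy of window lengths and sorting
the resulting eigenvalues into frequency bands, locally per level and then
globally across levels.

# The window model

Each window of length $w$ (time-mean $c_k$ removed) is approximated by a
rank-$r$ dynamic mode decomposition,

$$\tilde x_k(t) \;=\; \sum_{j=1}^{r} \varphi_j^k\, e^{\omega_j^k t}\, b_j^k
\;+\; c_k ,$$

with complex spatial modes $\varphi$ (unit 2-norm columns; magnitude and
phase are carried by $b$, with the phase tie-broken so each mode's
largest-magnitude entry is real-positive), continuous-time eigenvalues
$\omega$ and amplitudes $b$ defined at the window's local time origin
$t = 0$. Fixing the origin per window makes amplitudes comparable across
windows.

## Variable projection

The fit minimizes the Frobenius misfit by variable projection: for given
$\omega$ the linear coefficients solve the least-squares problem against
the exponential time basis $T(\omega)_{ij} = e^{\omega_j t_i}$ (via SVD
pseudoinverse, rank-truncated at $10^{-12}$ of the leading singular
value), and $\omega$ is refined by Levenberg–Marquardt steps on the
projected residual using the Kaufman approximation of the Golub–Pereyra
Jacobian. Defaults: initial damping 1.0, $\times 2$ on a rejected step,
$/3$ on acceptance, stop at $10^{-6}$ relative residual change or 100
iterations. Accepted iterations are monotone non-increasing in residual by
construction. Degenerate (duplicate-eigenvalue) bases are perturbed
deterministically and retried once; an all-zero window short-circuits to an
exact zero fit. For real input the spectrum is repaired to exact conjugate
symmetry by averaging matched pairs (tolerance $10^{-6}$), and eigenvalues
pairing with themselves are made purely real.

## Eigenvalue constraints

Physical systems do not sustain unbounded exponential growth, so the real
parts are restricted by projection (clamping) after every step — a choice
that preserves the variable-projection structure, unlike a penalty:

* `two_sided_small`: $|\mathrm{Re}\,\omega| \le \rho$ with the default
  $\rho = 1/(w\,\Delta t)$, one e-fold per window duration — "small but not
  exactly zero". This is the default for the smallest level, where short
  noisy windows otherwise produce wild growth/decay estimates.
* `nonpositive`: $\mathrm{Re}\,\omega \le 0$. The fixture configurations
  use this for pass-down levels. The reason is a practical optimization
  property we observed: the variable-projection Jacobian column of a mode
  scales with its amplitude, so a spare near-zero-amplitude pair whose
  initial guess sits at a spurious frequency moves very slowly, and with
  two-sided clamping active the optimizer can fail to migrate it to the
  near-DC drift it should absorb. A decay-only bound leaves that descent
  path open while still forbidding growth.
* `none`: unconstrained, for well-conditioned noiseless data.

## Initial guesses

Consecutive windows overlap and share dynamics, so each window warm-starts
from its converged predecessor. Cold starts (first window, or fallback)
take the eigenvalues of the best-fit one-step operator on a rank-$r$
projection of a *delay-embedded* copy of the window (up to 8 delays,
mapped to continuous time by $\log\lambda/\Delta t$). The embedding
matters twice: a standing wave is rank 1 in space and exposes no conjugate
pair to the plain one-step operator, and a generous delay count strongly
reduces the noise-induced damping bias of the estimated eigenvalues. A
warm-started window whose fit does not converge, or whose residual is both
above 5% and 1.3 times its predecessor's, is refit from a cold start and
the better fit kept — otherwise a warm-start chain can stay stuck in a
stale optimum after a transient switches on.

# Local scale separation

All $|\mathrm{Im}\,\omega|$ of a level are pooled and clustered by seeded
k-means after one of three transforms: `abs_im` (identity, the default and
usually the right local choice), `abs_im_squared`, or `log10_abs_im`
(floored at $10^{-12}$). The band count is either fixed a priori or swept,
with the mean silhouette width selecting the winner (sweep restricted to
$[2, \text{distinct} - 1]$; a single distinct value degenerates to one
band). Clusters are relabeled in ascending centroid order, so band 0
always holds the slowest frequencies — timescales longer than the window,
not resolvable at this level.

Band reconstructions sum each window's member modes (band 0 additionally
re-attaches $c_k$; any other band never does) and merge overlapping
windows with centre-peaked weights: windowed fits are robust near the
window centre and poor at its edges, so the default profile is a raised
cosine (Hann) over the window, floored at $10^{-3}$ so the blend's
denominator stays positive everywhere (this floor-and-normalize step *is*
the normalizing factor of the overlapped reconstruction); a Gaussian
profile is available. The band-0 reconstruction, including backgrounds, is
the pass-down: the exact input of the next, larger-window level. By
construction the band reconstructions of a level sum to its full blended
fit — a partition we test to $10^{-10}$ relative.

Windows advance by `stride` samples (default $w/8$, a balance of overlap
smoothness against cost; the stride must not exceed $w$ or samples would
go uncovered), and the tail window is shifted left so every sample is
covered by a full-length window.

# Global scale separation

Frequency content leaks between levels — a component resolvable at two
adjacent window lengths appears in both — so local bands cannot be read as
final. All eigenvalues in non-background local bands are interpolated to a
common reference time grid (the mean window times of the first, smallest
level) by nearest neighbour (ties to the earlier window), then clustered
on $\log_{10}|\mathrm{Im}\,\omega|$. The log transform is required here:
global bands span orders of magnitude, and on a linear scale the spread of
the fastest group dwarfs the separation of the slow ones (the acceptance
suite quantifies this: with three decade-spaced groups the log transform
selects $k = 3$ in 100/100 seeded replicates, the linear transform in 0).
Every original (level, window, pair) is then reindexed to the global band
with the nearest centroid. $G_0$ — never produced by clustering — is the
band-0 remainder of the largest level, including its backgrounds; it is
flagged not-well-resolved in summaries. Band reconstructions blend within
each level first and then sum levels (any ordering agrees for linear
weights; this one is fixed for reproducibility). Summaries report
centroids as both frequency ($10^{c}/2\pi$ cycles per time unit) and
period.

# Synthetic data and what the tests show

The generator plants spatially coherent components — Gaussian blobs,
plane waves, localized sine patches — each with a cosine oscillation below
Nyquist, an amplitude envelope (constant, periodic on/off gate, or ramp),
optional advection on a periodic spatial domain, plus seeded i.i.d.
Gaussian noise. Ground truth is exactly decomposable by construction.
Standard fixtures (all $\Delta t = 1$):

* `two_scale`: 0.2 and 0.002 cycles/sample, $n = 16$, $m = 4096$,
  noiseless; analysed with windows 64 and 1024 at rank 4 and two local
  bands per level.
* `three_scale_nonstationary`: adds 0.02 cycles/sample and gates the fast
  component 1024 samples on / 1024 off; the pass-down level uses rank 8
  and four local bands so the drift, slow, mid and leaked-fast content
  each have a home.
* `traveling`: a plane wave, wavelength 16 samples, speed 1.6
  samples/time ($0.1$ cycles/sample at a fixed sensor), $n = 32$,
  $m = 2048$ — one coherent mode pair, the case a windowed exponential
  model represents exactly.
* `noisy_two_scale`: `two_scale` plus white noise at 2:1 signal-to-noise
  variance ratio (noise sd $= \mathrm{sd(signal)}/\sqrt 2$), seed 202.

Problem sizes were chosen so the full suite and the acceptance script each
run in a few minutes on one CPU while still separating scales by two
decades. These fixtures emulate coherence, scale separation,
nonstationarity, translation and incoherent noise — they do *not* emulate
colored noise, irregular sampling, missing-sensor geometry, or the
continuum of scales of real turbulence, so passing tests demonstrate the
machinery, not field performance. On real data the practical levers are,
in order: rank, window lengths and count of levels, and the eigenvalue
constraint; fits should be judged against reconstruction error and
spectrum recovery (`relativeError()`, `psdCompare()`).

# Numerical choices and degenerate inputs

* Missing data must be resolved before fitting: runs of gaps up to a
  caller-set duration are linearly interpolated per row; longer runs,
  edge runs, and all-missing rows stay flagged and the solver refuses
  masked input.
* Multi-variable records are stacked along the space axis (row-major per
  variable); optional per-variable standardization (off by default,
  recorded for inversion) prevents unit mismatches from dominating joint
  fits.
* k-means runs Lloyd's algorithm with seeded restarts; with
  duplicate-heavy one-dimensional data a restart can propose an empty
  cluster, in which case a deterministic quantile-seeded start is used.
  A winning silhouette below 0.5 triggers a low-confidence warning, not
  an error.
* All randomness (k-means restarts, noise fields) derives from explicit
  seeds carried in the configuration; two runs with the same
  configuration are bit-identical, which the suite checks by comparing
  serialized archives.
* The model archive is a single versioned JSON file (`costsep-1`),
  complex arrays split into real/imaginary parts, written at full
  precision (reconstructions survive a round trip to better than
  $10^{-12}$ relative; negative zeros are normalized so re-saving a
  loaded model is byte-identical). JSON was chosen over a binary
  container for portability and text-only tooling; wide CSV covers
  snapshot input/output.
* Window index bookkeeping is 1-based inclusive `[start, end]`, the R
  convention; the generated windows are positionally identical to a
  0-based half-open formulation.

# Limitations

The decomposition is diagnostic, not predictive: nothing extrapolates
beyond the record. It is not a perfect decomposition — content that is
spatially incoherent (noise; this is the desirable side) or unresolvable
at every configured window length is simply absent from the fit, so the
reconstruction must be checked before interpretation. Estimates inside the
cone of influence (the first and last $w/2$ samples per level) are
unreliable, increasingly so at the largest level. Rank is a fixed budget
per level: when the number of active components varies over the record,
spare mode pairs wander in frequency with near-zero amplitude; they are
harmless in reconstructions but can seed spurious low-variance bands, so
band tables should be read together with their variance shares. Physical
labeling of bands is left to the user.
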