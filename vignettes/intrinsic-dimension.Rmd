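---
title: "Estimating intrinsic dimension: models, parameters and design choices"
author: "idest package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intrinsic dimension: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idest)
```

# The problem

A point cloud of $M$ observations in $p$ features often lies near a
structure whose *intrinsic dimension* (ID) $n$ is much smaller than $p$:
a manifold, a union of manifolds of different dimension, or — when no
manifold assumption is made — simply a distribution whose geometric
fingerprints (covariance pattern, neighbor-distance ratios, linear
separability) match those of a reference $n$-dimensional model. `idest`
implements estimators of both kinds behind one interface, together with
a per-point *local* driver, generators of benchmark manifolds with known
dimension, and a meta-analysis layer for profiling collections of
datasets.

Because each estimator keys on a different fingerprint, different
estimators legitimately disagree; the package treats the full profile of
estimates, and its consensus summary, as the robust description of a
dataset's dimensionality.

# Estimator families and their assumptions

## Eigenvalue-spectrum (PCA) criteria

`covarianceSpectrum()` returns the eigenvalues of the sample covariance
(normalization $1/(M-1)$; values below $10^{-12}\lambda_1$ are clamped
to zero as numerical noise). `pcaDimension()` maps a spectrum to a
dimension by one of seven classical rules (Fukunaga–Olsen, Fan, maximum
gap, explained-variance ratio, participation ratio, Kaiser, broken
stick). These criteria assume the structure is *linear*: they read the
flat dimension of the spanned subspace, not the dimension of a curved
manifold (a swiss roll reads 3, not 2). That mismatch is informative —
the gap between linear and nonlinear estimates measures curvature — and
is why the profile view matters.

Two rules deserve comment, as the published descriptions are loose about
rank-deficient spectra:

* **Fan** requires *both* a large consecutive-eigenvalue gap
  ($\lambda_i/\lambda_{i+1} > R$, default $R = 10$) and sufficient
  cumulative variance ($\ge C$, default $C = 0.8$) at the selected
  index. With an "either" rule, five exactly equal nonzero eigenvalues
  would trigger the cumulative condition one component early (cumulative
  share $0.8$ at $i = 4$) and *misread an exact rank-5 spectrum as 4*;
  the conjunctive rule recovers the rank exactly, which is the behavior
  a rank criterion must have on noiseless input.
* **maxgap** maximizes consecutive *ratios* (not differences — ratios
  make it scale-invariant). When the spectrum is rank-deficient the gap
  into the zero block is infinite and wins, so the criterion returns the
  exact rank $p'$; restricting the search to the nonzero block would
  make the answer depend on sampling noise among the nonzero
  eigenvalues.

Counting criteria report at least 1 on any nonzero spectrum: a strict
Kaiser or broken-stick count can be 0 on a perfectly flat spectrum, but
dimension 0 is not a meaningful answer for a non-degenerate cloud.
Thresholds ($\alpha_{FO} = 0.05$, $\tau = 0.95$, Fan's $R$ and $C$) are
standard conventions and configurable; the participation ratio is
reported continuous (a `round` flag exists but is off by default, since
the continuous value carries the information).

## Nearest-neighbor and fractal estimators

These assume local uniformity: inside a small ball the cloud looks like
a uniform sample from an $n$-dimensional ball, so ratios of neighbor
distances have known distributions.

* **MLE** (`mleID`): per point, the inverse estimate is the mean log
  ratio $m(x) = \frac{1}{k-1}\sum_j \ln(r_k/r_j)$. The default
  aggregation averages the *inverse* estimates over all points and
  ranks and inverts once — the standard correction that removes the
  small-$k$ bias of averaging per-point estimates directly (the
  uncorrected `mean_of_locals` variant is kept for comparison).
* **TwoNN** (`twoNN`): uses only $\mu = r_2/r_1$, Pareto-distributed
  with shape $n$ under local uniformity; robust at very small scales.
  Default fit is the regression through the origin of
  $-\ln(1 - F̂(\mu))$ on $\ln\mu$ with plotting position $i/M$, after
  discarding the largest 10% of ratios (the tail is most sensitive to
  density variation); an MLE fit is available.
* **MADA** (`mada`): doubling rule $\ln 2 / \ln(r_k/r_{\lceil k/2\rceil})$
  per point, aggregated by mean (median available). Points with tied
  radii are invalid and *counted* (`params$invalidFraction`) rather than
  propagated as NaN.
* **MOM** (`momID`): first-moment matching, $d = m_1/(w - m_1)$ with
  $w = r_k$.
* **CorrInt** (`corrInt`): two-scale slope of the correlation integral,
  with scales set to the mean $k_1$-th and $k_2$-th neighbor distances
  and exact brute-force pair counts. A two-scale slope is the simplest
  faithful reading of a two-parameter $(k_1, k_2)$ interface; a full
  radius-grid regression is a straightforward extension point.
* **TLE** (`tleID`): inside each k-NN ball, *every ordered pair* of
  neighbors (and the reflections of targets about the query point)
  contributes the log of its distance normalized by the distance from
  the viewpoint to the ball boundary along the ray through the target;
  under local uniformity that normalized distance to the power $n$ is
  uniform, so the estimate is the negative reciprocal of the mean log
  term. Using all pairs extracts far more information from a tight
  locality than query-centered ratios alone. All pairs with positive
  distances are kept (the geometric constraint $D \le t$ holds up to
  rounding), which keeps the term set — and hence the estimate — exactly
  stable under rigid motions and rescaling.
* **MiND** (`mindML`): likelihood of $\rho = r_1/r_k$ under
  $g(\rho) = k n \rho^{n-1}(1-\rho^n)^{k-1}$, maximized over integers
  (`MLi`) or continuously on $[1, D_{\max}]$ (`MLk`). Ratios exactly 0
  or 1 carry no information and are dropped with a count.
* **KNN graph scaling** (`knnGraphID`): the total edge length of the
  k-NN graph grows as $n_q^{1-\gamma/d}$; bootstrapped subsamples at
  several sizes give the log-log slope $a$ and $d =
  \mathrm{round}(\gamma/(1-a))$. Slope $a \ge 1$ is reported invalid.

## Concentration-of-measure estimators

* **FisherS** (`fisherS`): after centering, whitening the
  well-conditioned components (condition cap 10) and projecting to the
  unit sphere, the fraction of point pairs with inner product above
  $\alpha$ is compared with the exact spherical-cap probability for
  uniform unit vectors in $n$ dimensions,
  $p(\alpha, n) = \tfrac12 I_{1-\alpha^2}\!\big(\tfrac{n-1}{2},
  \tfrac12\big)$, strictly decreasing in $n$; the estimate is the
  continuous root, found by bracketed bisection with a geometrically
  grown upper bracket (so the log never underflows). The exact
  incomplete-beta form is used rather than its large-$n$ asymptotic —
  they agree asymptotically, and the exact form is correct at the small
  dimensions where the asymptotic is visibly off. The default threshold
  is fixed at $\alpha = 0.8$; the `auto` rule picks the grid $\alpha$
  closest to the center of the range where the observed fraction is
  strictly inside $(0,1)$ (both selection rules are artifact choices,
  stated as such).
* **ESS** (`essID`): the mean $|\sin\theta|$ over pairs of centroid-
  anchored vectors grows with dimension toward 1; the theoretical curve
  is the Wallis-integral ratio
  $T(n) = \Gamma(n/2)^2 / (\Gamma(\tfrac{n+1}{2})\Gamma(\tfrac{n-1}{2}))$
  with $T(1) = 0$, $T(2) = 2/\pi$, $T(3) = \pi/4$, strictly increasing;
  the estimate is the piecewise-linear inverse over integer knots,
  clamped to $[1, p]$, with exact snapping at the knots. Only the
  pair/angle (simplex order 1) version is implemented; higher simplex
  orders are out of scope. Pairs are capped at $10^5$ (seeded sampling
  beyond that).
* **DANCo** (`danco`): two statistics — the continuous MiND dimension of
  $\rho = r_1/r_k$, and a von Mises location–concentration fit of
  pairwise neighbor angles — are compared, via a numerically integrated
  KL term for the $\rho$ densities plus the closed-form von Mises KL,
  against the same statistics on seeded calibration samples drawn
  uniformly from the $d$-sphere for every candidate $d$; the estimate is
  the KL-minimizing candidate. Calibration samples are cached per
  $(d, k, n_{calib}, seed)$. The default calibration (100 points, one
  replicate) favors desk-scale runtime over fidelity — increase
  `nCalib` for sharper calibration on hard inputs.

ESS and DANCo are the expensive estimators ($O(M^2)$ pairs;
per-candidate calibration); they refuse inputs beyond their caps
(2000×20 and 10,000×100) unless forced, and the profiling layer reduces
such inputs with PCA-derived coordinates and seeded row subsampling
before calling them.

# Local estimation

`estimateLocal()` applies any global estimator to the sub-cloud of each
point and its $k$ nearest neighbors. Two conventions matter:

* With $k = M - 1$ every sub-cloud is the whole dataset and the local
  field degenerates to the global estimate — a useful sanity check that
  holds exactly.
* A wrapped method's own neighborhood parameter is clamped to at most
  half the sub-cloud size. Hill-type estimators need the $k$-th neighbor
  distance to sit inside the bulk of the sample; applied naively with
  $k_{inner} = M_{sub} - 1$, every reference radius is the sub-cloud
  diameter and local MLE on a uniform 2-sphere reads ~1.4 instead of 2.
  With the half-size clamp it reads ~2.0, and over 95% of per-point
  values fall in $[1.5, 2.5]$ at $n = 2000$, $k = 20$.

Per-point failures (for instance duplicated points in a neighborhood)
carry status codes in the `LocalIDField`, never silent NaN.

# Synthetic generators: what they do and do not emulate

The `generateManifold()` registry draws uniform samples from supports of
known dimension — balls, spheres, cubes, Gaussians, swiss roll, Möbius
band, helix, a `tanh`-of-linear sphere embedding, exact affine
subspaces — plus the labeled line–disk–ball benchmark whose three
segments (local ID 1, 2, 3) sit at fixed disjoint offsets so default
neighborhoods never mix segments. All draws are seeded and byte-
reproducible; optional isotropic Gaussian ambient noise is off by
default. The registry is an extension point: further benchmark maps are
added mechanically as new entries.

The `affine_subspace` generator accepts `isotropic = TRUE`, which
whitens the latent sample exactly so the embedded spectrum has $d$
*equal* nonzero eigenvalues. This is the right fixture for exact-rank
tests: with i.i.d. latent coordinates the sample variances differ and
the participation ratio of a rank-5 cloud is ~4.97, not 5; only the
isotropic construction makes "all criteria read exactly 5" a
well-posed expectation.

These generators emulate *uniform, noiseless (or weakly noisy), single-
or few-component* supports. Real omics data have density gradients,
heteroscedastic noise, discrete/zero-inflated coordinates and mixed
local dimension. Passing the recovery tests here therefore shows the
estimators are correctly implemented and calibrated on their own model
assumptions; it does not promise accurate IDs on data that violate
those assumptions — which is precisely why the profile/consensus layer
reports many estimators side by side.

# The meta-analysis layer

`runProfile()` preprocesses each dataset (min/max scaling to $[0,1]$;
removal of approximate duplicate rows and columns at Chebyshev tolerance
$10^{-8}$ on the scaled matrix — "approximately non-unique" is not a
quantified notion, so the tolerance is an explicit, documented default;
seeded subsampling above 100,000 rows), applies per-method caps (20,000
rows for KNN and MADA; 10,000×100 for DANCo; 2000×20 for ESS), and runs
every estimator, recording value, status and rows used per cell. A
failing cell never aborts the batch. Identical seeds give byte-identical
profiles.

`imputeProfile()` fills missing cells by deterministic chained least
squares: initialize at column means, then repeatedly regress each
incomplete column on all others over its observed rows until the largest
change falls below $10^{-6}$. It is a deliberately simple, fully
specified and testable scheme of its own (on exactly proportional
columns it reproduces the proportional prediction to $10^{-6}$).
Imputation runs on raw values; z-scoring happens afterwards in
`consensusID()` — scaling first would let incomplete columns distort
their own standardization.

`consensusID()` z-scores columns, averages per dataset (the consensus
score — negative means lower-dimensional than the collection average),
and runs a PCA of the z-scored profile; the loading sign convention
makes each component's largest-magnitude loading positive. It accepts
two datasets (the scores are then $\pm$ equal by construction), though
meaningful consensus needs more. `redundancySensitivity()` reports
ID([X X])/ID(X): exactly 1 for relative-eigenvalue criteria (the
spectrum of $[X\,X]$ is $\{2\lambda_i\}\cup\{0\}$), ~1 for distance-
ratio methods (all pairwise distances scale by $\sqrt2$), and
legitimately far from 1 for count-based spectral criteria — that
difference is the measurement. `fitTimeModel()` fits
$\ln t = \ln c + \alpha\ln N_{obj} + \beta\ln N_{var}$ by OLS; timing
*collection* is hardware-dependent and deliberately untested, while the
fit itself is exact on noiseless records.

# Numerical conventions

* k-NN search is exact brute force (compiled), ties broken by lower row
  index; duplicate points stay in the table and each estimator decides
  whether zero distances are degenerate for it.
* A single status vocabulary — `ok`, `invalid_nan`, `invalid_negative`,
  `invalid_infinite`, `degenerate_input` — with the invariant that `ok`
  means finite and positive. Estimators never return bare NaN or
  infinities.
* All stochastic steps take explicit integer seeds (default 0) and
  restore the caller's RNG state.
* Default neighborhood sizes ($k = 20$ for MLE/MOM/MADA/TLE, $k = 10$
  for MiND and DANCo, $k_1 = 10, k_2 = 20$ for CorrInt, $k = 5$ for the
  graph estimator) are artifact choices in the range the source methods
  conventionally use; they are parameters, not constants.
* Likelihood maximizations over candidate dimension are bounded by the
  ambient dimension by default.

Test problem sizes (balls of $n = 2500$ for recovery, $n = 2000$ for
local fields, collections of a few hundred points for the batch layer)
are chosen so the whole suite exercises every code path at comfortable
desk scale while keeping each estimator well inside its asymptotic
regime.

# Known limitations

* Euclidean metric only (the interface leaves the metric argument as an
  extension point); no sparse-matrix or approximate-neighbor support.
* PCA criteria read linear dimension; on curved manifolds they
  systematically exceed nonlinear estimates.
* DANCo's reduced default calibration trades sharpness for speed;
  near-ambient dimensions on small samples may be off by one.
* The correlation-dimension implementation uses two scales, not a
  radius-grid regression.
* The imputation scheme assumes approximately linear relations between
  method columns, which holds for profiles of related estimators but is
  an assumption, not a theorem.
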