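---
title: "Elastic shape analysis of protein backbones: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic shape analysis of protein backbones: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esaprot)
```

## The model

A protein backbone is treated as an open parameterized curve
$\beta : [0,1] \to \mathbb{R}^3$, sampled at its backbone atoms (N, CA, C,
or the CA trace alone). Shape is what remains after discarding translation,
scale, rotation, and parameterization. The package represents each curve by
its square-root velocity function (SRVF)

$$q(t) = \frac{\dot\beta(t)}{\sqrt{\lvert\dot\beta(t)\rvert}},$$

which removes translation and turns the elastic metric — the natural
Riemannian metric that charges separately for local bending and local
stretching — into the ordinary $\mathbb{L}^2$ metric. After rescaling the
curve to unit length, $\int_0^1 |q(t)|^2\,dt = 1$, so unit-length curves
live on the unit sphere of $\mathbb{L}^2([0,1],\mathbb{R}^3)$ (the
*preshape sphere*). Rotations $O \in SO(3)$ and reparameterizations
$\gamma$ act on SRVFs by $q \mapsto O\,(q\circ\gamma)\sqrt{\dot\gamma}$;
the *shape space* is the quotient of the preshape sphere by these actions,
and the distance between two shapes is

$$\theta = \arccos\,\langle q_1,\; O^*(q_2\circ\gamma^*)\sqrt{\dot\gamma^*}\rangle,$$

the great-circle arc length to the best rotated and reparameterized
representative of the second curve. Unlike RMSD over a chosen atom subset,
$\theta$ is a proper metric: symmetric, zero only for equal shapes, and
satisfying the triangle inequality, which is what makes downstream
statistics (means, covariances, Gaussian-type models, clustering)
mathematically coherent.

The optimal rotation given a correspondence is closed-form (SVD of the
$3\times 3$ cross-covariance $\int q_1 q_2^{\mathsf T}dt$, with the
determinant sign-corrected to exclude reflections). The optimal
reparameterization given a rotation is found by dynamic programming over
monotone lattice paths. The two steps are alternated to a local optimum.

## Numerical and design choices

**Grids and quadrature.** All SRVFs are sampled on a uniform grid on
$[0,1]$ (default $m = 100$ points per curve; configurable everywhere).
Inner products and norms use trapezoidal quadrature with one shared weight
vector, so normalization, projection, and distances are mutually
consistent. Derivatives are central differences in the interior and
one-sided at the endpoints; exactly repeated consecutive points are
collapsed before differentiation and zero-speed samples map to $q = 0$,
the limiting value.

**Arclength canonicalization.** Before conversion to an SRVF, each curve
is resampled at uniform *arclength* rather than at its deposited
parameters. The elastic matching optimizes over reparameterizations
anyway, so the starting parameterization is mathematically irrelevant, and
canonicalizing makes it numerically irrelevant too: two parameterizations
of the same polyline give bit-identical inputs, and the reported distance
is exactly reparameterization invariant rather than invariant only up to
the dynamic-programming resolution. This matters for CA polylines, whose
direction field turns by roughly 100 degrees per residue: without
canonicalization, the residual of matching a curve against a rewarped copy
of itself decays only slowly with grid size.

**The dynamic program.** The matching function $\gamma$ is a monotone
lattice path from $(0,0)$ to $(1,1)$ with steps $(\Delta i, \Delta j)$,
$\Delta i, \Delta j \in \{1,\dots,4\}$ and $\gcd = 1$ (duplicate slopes
removed), so local slopes range over $[1/4, 4]$. An edge is priced by
trapezoidal quadrature of $|q_1 - \sqrt{\dot\gamma}\,q_2(\gamma)|^2$ with
$\gamma$ linear on the edge and $q_2$ linearly interpolated. Ties prefer
diagonal (identity-like) steps. On small grids the program provably equals
exhaustive enumeration over all monotone paths; the test suite checks this
to $10^{-12}$ on 8–10-point grids.

**Alternation, seeding, and the group action.** Rotation and
reparameterization steps are alternated until the cost decrease falls
below $10^{-5}$ (at most 15 rounds); a step is accepted only if it lowers
the cost, so each cost trace is non-increasing by construction. Two
implementation hazards shaped the design. First, the joint problem is
non-convex: helical shapes can trap a rotation step in a *phase-shifted*
rotation (compensating a shift along the helix instead of aligning the
fold). The alternation is therefore seeded from several informative
initial rotations — identity, the rigid Kabsch superposition of the curve
coordinates, and the four proper principal-axes alignments — taking the
best after one reparameterization step each. Second, the discrete group
action must not be applied incrementally: warping a sampled SRVF through
linear interpolation low-pass filters it, and iterating such warps makes
any two curves drift spuriously closer. The optimizer instead keeps the
*total* transform $(O, \gamma)$ and re-applies it once per iteration to
the original curve representative (sampling the polyline, which keeps the
points on the polyline, then recomputing the SRVF), so interpolation
error stays bounded.

**Symmetry.** Every feasible $(O, \gamma)$ yields an upper bound on the
shape distance, and aligning $q_2$ onto $q_1$ explores a different
discrete feasible set than the reverse. `geodesic_distance()` optimizes
both directions and reports the smaller bound, which is the better
estimate and makes the reported distance exactly symmetric in its
arguments. `align()` additionally returns a transform-consistent
representative ($\theta = \arccos\langle q_1, q_2^\*\rangle$ holds for
the returned $q_2^\*$), transferring the better direction's solution by
inverting the group element and re-polishing when needed.

**arccos clamping.** Inner products are clipped to $[-1, 1]$ before
`acos` so round-off cannot produce `NaN` at $\theta \approx 0$.

**Karcher mean.** The mean shape minimizes $\sum_i \theta_i^2$. Every
iteration re-aligns each shape to the current mean, averages the log-map
images in the tangent space, and takes an exponential-map step (initial
step 0.5, halved whenever the objective would increase; tolerance
$10^{-5}$ on the mean tangent norm, at most 50 iterations). The
initialization is the preshape-projected extrinsic average of the shapes
aligned to the first one. For two shapes this lands numerically on the
midpoint of their connecting geodesic, as it must.

**Covariance and sampling.** Tangent vectors are flattened to $3m$
coordinates scaled by the square roots of the quadrature weights, so
Euclidean operations in the flat space equal $\mathbb{L}^2$ operations on
the grid; the sample covariance is eigendecomposed as $K = U\Sigma U^{t}$
and directions with variance above $10^{-12}$ (at most $n-1$) are kept.
The $\sigma_j$ are treated as variances: sampling draws
$v = \sum_j z_j \sqrt{\sigma_j}\,U_j$ with $z_j \sim N(0,1)$, and the
principal-direction sweep uses $t\sqrt{\sigma_j}U_j$ for $t \in [-2,2]$.
`tangent_density()` evaluates the $k$-dimensional Gaussian density of the
projected log-map coordinates; it is a density on the tangent space, not a
normalized probability over shapes, so only *comparisons* between
densities under the same model are meaningful.

**Per-residue flexibility.** `residue_variance()` samples structures from
the fitted model, superposes each onto the mean curve (common centroid,
rotation from SRVF alignment), and pools the squared deviations of the
grid points that belong to each residue (nearest-parameter assignment).

## The synthetic generators

`make_curve()` produces backbone-like CA polylines: an ideal alpha helix
(radius 2.3 Å, rise 1.5 Å per residue, 3.6 residues per turn, giving
CA–CA spacing near 3.8 Å), rigidly bent helices, helix–turn–helix shapes,
beta-hairpin-like strand pairs, and seeded smooth random curves. These
mimic the geometry of small protein folds, not their energetics: there is
no excluded volume, no hydrogen bonding, and no side-chain physics.

`make_ensemble()` emulates an NMR-style ensemble: Gaussian perturbations
of a known mean shape along a small number of orthonormal tangent
directions with geometrically decreasing scales
($\mathrm{sd}_j = \mathrm{noise\_sd}\cdot 2^{-(j-1)}$, default three
modes), optionally confined to a parameter interval such as the last 20%
of the chain to imitate a flexible C-terminus. The default scale
`noise_sd = 0.1` radian of arc produces member-to-mean distances around
0.1 — an order of magnitude below the distances separating the distinct
synthetic folds, mimicking the tight-ensemble/distinct-fold separation of
real structure sets; the classification benchmark uses 0.06 so that
families are tight but clearly non-degenerate.

One generator subtlety is load-bearing: the ground-truth perturbation
directions are constructed *orthogonal to the orbit* of the
shape-preserving transformations at the mean — the span of the rotation
generators $E\mu$ and of reparameterization flows
$\dot\mu\,b + \tfrac{1}{2}\mu\,\dot b$ — as well as to $\mu$ itself.
Variation placed along those orbit directions is invisible in shape space
(alignment removes it), so a generator that injected it would define a
ground truth no estimator could recover. With horizontal directions, the
Karcher mean, the top principal direction, and the sampling covariance are
all recoverable, and the tests verify this quantitatively (mean within
$\theta \le 0.05$ at $n = 50$, top-direction cosine $\ge 0.95$, Monte
Carlo covariance within 10% Frobenius error at 5,000 draws).

What passing these tests shows — and does not show. They validate the
estimators under the generating model (tangent Gaussians around a known
mean). Real ensembles have non-Gaussian, physically constrained
variability; performance there depends on how well a unimodal tangent
Gaussian approximates it, which the synthetic suite cannot certify.

## Problem sizes used by the tests and acceptance script

The shipped checks use 20 synthetic curves at grid 80 for the
metric-axiom suite, $3\times 10$ members at grid 80 for the clustering
benchmark, $n = 50$ ensembles at grid 100 for recovery, and 5,000 draws
for the Monte-Carlo covariance check; these sizes were chosen to estimate
each quantity stably while keeping a full run in the minutes range on one
core. Worked-example comparisons against deposited structures (1MP6 vs
1G1J/2K98/2EOW, and 1ycc vs 1gu2) run only when the corresponding PDB
files have been downloaded into `inst/extdata/pdb/` (see the README
there); coordinate files are not redistributed with the package.

## Known limitations

- The quotient by reparameterization is approximated on a lattice; very
  strong local compressions (slopes outside $[1/4,4]$) are not
  representable, and distances carry a discretization bias of order the
  grid spacing. The printed third decimal of a distance is not meaningful
  at $m = 100$.
- The alternation optimizes rotation and reparameterization jointly only
  to a local optimum; the two-schedule restart removes the common helical
  failure mode but is not a global guarantee.
- Alignment is sequential along the chain: circular permutations, domain
  swaps, and non-sequential structural equivalences are out of scope, as
  are auxiliary per-residue channels (secondary structure, sequence
  profiles) that could be concatenated to the geometry.
- `tangent_density()` values depend on the retained subspace and carry no
  absolute normalization over shapes; use them only to rank shapes under
  one fitted model.
- The Gaussian tangent model is unimodal by construction; multimodal
  conformational distributions would need mixture extensions.
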