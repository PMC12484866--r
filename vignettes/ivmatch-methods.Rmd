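---
title: "Methods: image-varifold matching, censoring, resampling and feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-varifold matching, censoring, resampling and feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the models implemented by `ivmatch`, the tunable
parameters and their defaults, the numerical choices made where the design
was genuinely open, and what the synthetic phantoms do and do not
demonstrate about real data.

## The measure model and its norm

All data — molecular detections, segmented cells, and labeled atlas
voxels — are represented as particle measures
$\mu = \sum_i w_i \delta_{x_i} \otimes p_i$ on position $\times$ feature
space.  Positions are in millimeters everywhere; readers convert micron
inputs on the way in (`read_particles(unit = "um")`).  Feature rows may be
stored normalized (probability distributions) or unnormalized (weighted
laws $w_i p_i$); the flag is recorded and the code never renormalizes
silently, because the resampling objective and the atlas laws both operate
on unnormalized laws.

Similarity is the reproducing-kernel inner product
$\langle\mu,\nu\rangle = \sum_{ij} w_i w_j K_\sigma(x_i,x_j)\,
(p_i \cdot p_j)$.  The spatial kernel is a sum of Gaussians — brain-scale
matching typically mixes a fine and a coarse bandwidth (e.g. 0.15 mm and
0.75 mm) — and the feature kernel is the indicator kernel for discrete
labels or the plain Euclidean inner product for real-valued features; both
reduce to the dot product of the stored feature rows, which is how the
double feature sum is evaluated.  Kernel sums accept an optional
truncation radius (default $4\sigma$ when enabled; exact evaluation is the
default) implemented as a hard zero beyond the radius on the pairwise
distances, so that truncated and exact sums agree exactly whenever all
pairs fall inside the radius — the property the test suite asserts.

Diffeomorphisms act by
$\varphi\cdot\mu = \sum_i |D\varphi|_{x_i} w_i \delta_{\varphi(x_i)}
\otimes p_i$: mass is transported with the local volume change and feature
distributions ride along unchanged.

## Geodesic shooting

Deformations are generated by flows of Gaussian-kernel velocity fields
parameterized by initial space momenta $\rho^x_i$ (3-vectors) and mass
momenta $\rho^w_i$ (scalars):
$$v(x) = \sum_i k_\sigma(x,x_i)\rho^x_i +
  \frac{x-x_i}{\sigma^2} w_i \rho^w_i k_\sigma(x,x_i),$$
with the reduced Hamiltonian
$H = \tfrac12\sum_i \rho^x_i\cdot v(x_i) + \rho^w_i\,\mathrm{div}\,
v(x_i)\,w_i$ and dynamics $\dot x = v$, $\dot w = (\mathrm{div}\,v)\,w$,
$\dot\rho = -\nabla_q H$.  Both momenta are always carried.

Numerical choices:

- **Integrator.** Fixed-step RK4 with `n_steps = 10` by default.  The
  choice is validated by the conservation tests: relative Hamiltonian
  drift below $10^{-3}$ at 10 steps and below $10^{-4}$ at 40 on a
  20-particle geodesic, decreasing with step count as the order predicts.
- **Gradients.** $\nabla_q H$ is implemented analytically (the closed
  forms follow from differentiating the pairwise Gaussian terms) rather
  than by automatic differentiation; the test suite verifies the analytic
  expressions against central finite differences to $10^{-7}$, which makes
  the hand derivation as trustworthy as AD while keeping the dependency
  footprint to base R.
- **Jacobians.** $\log|D\varphi|$ is integrated alongside the state with
  the same RK4 stages ($d\log|D\varphi|/dt = \mathrm{div}\,v$), which
  remains well defined for zero-weight particles; $w_i(1)/w_i(0)$ agrees
  with it to integrator accuracy.
- **Blow-up.** A degenerate trial step during optimization (overflowing
  positions or Jacobians) scores a large finite penalty ($10^{10}$)
  instead of aborting, so line searches simply back off.

## Matching problems and the optimizer

Single-modality matching minimizes $H(q_0,\rho_0) +
\|\varphi_1\cdot\mu-\mu'\|^2_M$ over initial momenta.  Cross-modality
matching augments the atlas with latent per-region laws $p_\ell$ over the
target features and minimizes
$$H + \sum_\ell J_{KL}(p_\ell) +
  \|\varphi_1\cdot\mu_A^{p,\lambda}-\mu_T\|^2_M \;(+\,J_s(\lambda)),$$
jointly over momenta, laws, and (when censored) the bandwidth $\lambda$.
The KL prior weights each region by its deformed mass relative to the
total target mass, is zero exactly at uniform laws, and uses the
$0\log 0 = 0$ convention.  Regions with no membership mass are pinned to
the uniform law with a warning.

- **Optimizer.** `stats::optim(method = "L-BFGS-B")` with an increased
  memory (`lmm = 20`) and a tight relative tolerance.  The iteration
  budget defaults to 150, the budget at which the mapping problems in this
  package's tests converge.
- **Gradients.** The law block has an exact analytic gradient (the data
  term is quadratic in the laws and the KL gradient is
  $\propto \log(\bar p_\ell |\mathcal F|)$); momenta (and $\log\lambda$)
  use forward differences.  A consistency test checks the assembled
  gradient against central differences.
- **Positivity.** Laws are parameterized as $p_\ell = e^{\theta_\ell}$ so
  the optimizer is unconstrained; weights in the resampler use the same
  device.
- **Law warm start.** With the deformation held at its initial value the
  law subproblem is a small smooth convex program (the geometry-dependent
  kernel matrices are computed once), so the laws are first optimized
  alone and the joint descent starts from that point.  From a uniform
  start the joint L-BFGS path crawls through a poorly conditioned valley;
  warm-starting removes that plateau without changing the (single, joint)
  optimization scheme or its optimum — the warm start is an
  initialization, not an alternating scheme.
- **Loss weights.** The relative weight of the regularization and data
  terms is exposed (`reg_weight`, `data_weight`, both default 1).  Note
  that because the laws are unnormalized, a uniform density mismatch
  between atlas and target within a region is absorbed by the law scale
  rather than by volume change of the map — deformations are driven by
  spatial structure, not by global density offsets.
- **Rigid/similitude pre-alignment** (`fit_similitude()`) is available as
  an optional coarse stage (rotation + isotropic scale + translation
  minimizing the same varifold loss, axis-angle parameterization); the
  synthetic problems in the tests start close enough that it is off by
  default.

## Censoring

The planar censor is
$\alpha^\lambda(x) = \tfrac12[\tanh(\langle x-a_0,n_0\rangle/\lambda) +
\tanh(\langle x-a_1,n_1\rangle/\lambda)]$ with anchors on the first and
last measured sections and inward unit normals; values are clipped to
$[0,1]$.  The bandwidth penalty
$J_s(\lambda) = \tfrac{\lambda^2}{0.1}\ln\tfrac{\lambda^2}{0.1} + 1 -
\tfrac{\lambda^2}{0.1}$ is zero exactly at $\lambda^2 = 0.1$ and tends to
1 as $\lambda \to 0$; $\lambda$ is estimated jointly with the map.

For irregular boundaries the censor is a small fully connected classifier
($3\to15\to5\to1$, exponential-linear activations) whose output passes
through a $\tanh$ at temperature $\lambda$ rescaled to $[0,1]$.  Training
uses weighted binary cross-entropy (the stated class weighting, 1000:1 by
default, balances the interiors' numerical dominance; the synthetic tests
use balanced classes) with manual backpropagation and L-BFGS-B; inputs are
standardized for conditioning and the scaling is folded back into the
first layer, so the stored parameters act on raw coordinates.  The loss
and optimizer are choices of this package — only the architecture and the
class weighting are fixed by the design.  Training is deterministic given
the seed.  Rostral/caudal closure of a section stack is handled by placing
dummy label-0 sections beyond the first and last sections when building
the training set.

## Scale-space resampling

The approximation at scale $\sigma$ minimizes
$\|\mu_\sigma - \mu\|^2_M$ over particle positions and weighted laws.
The three stages are: (1) lattice initialization — cube edge equal to
$\sigma$ (the proportionality constant is configurable), one particle per
occupied cube placed at a seeded random member particle, cube mass summed,
uniform law; (2) weights/laws optimization at fixed positions; (3) joint
optimization.  Both optimization stages use analytic gradients and 200
iterations by default with early stopping on relative objective change
below $10^{-7}$.  Total mass is a free variable — the tests measure its
drift and bound it by 2% rather than assuming conservation.

Baselines: K-means via `stats::kmeans(algorithm = "Lloyd")` on positions
only (feature mass aggregated per cluster afterwards — deliberately
reproducing that scheme's blindness to features), with empty clusters
handled by re-seeding the initialization; and fixed-grid kernel
redistribution with per-particle normalized weights, which conserves mass
exactly.  Scheme comparisons share the particle budget by reusing the
occupied-cube lattice for the grid baseline and setting K to the optimized
scheme's particle count.

## Mutual-information feature selection

Counts are rasterized onto $\sigma\times\sigma$ squares (default
$\sigma = 0.05$ mm) with a half-open assignment convention, then
quantile-binned per feature using the empirical CDF over occupied squares
only — including the empty exterior would swamp the quantiles.  The
score of a feature is the conditional mutual information
$I(X; M^g \mid C)$ over the uniform ensemble of megasquares ($2K\times 2K$
squares, all fully contained placements at stride 1), squares within them,
and split directions; $X$ is the half (left/right or bottom/top) the
square falls in.  Defaults $q = 10$ quantiles and $K = 4$; natural
logarithm (the base only rescales ranks); squares outside the tissue mask
contribute zero-count bins.  The implementation is verified against an
exhaustive enumeration of the sample space on small grids, exactly.
Scores are reported as the mean per-megasquare conditional MI; per-section
scores aggregate by summation, with features missing from a section
contributing zero.  Ranking is by descending score with lexicographic
tie-breaking.

## Rigid stack alignment

Sections are centered at their mass-weighted centroids on load; the first
and last sections are fixed and all interior rotations and translations
are optimized simultaneously (the objective is joint) against the sum of
adjacent-pair varifold distances.  The default spatial bandwidth is twice
the median nearest-neighbor distance of the first section.  Rotationally
symmetric sections admit multiple optima; the phantoms are asymmetric by
construction and the implementation reports the local optimum reached from
the identity initialization.

## Synthetic phantoms: what they emulate and what they do not

- `make_three_region_toy()` — a three-region square atlas and a two-feature
  target homogeneous per region, related by a half turn; the partition is
  asymmetric so the half turn is the unique aligning rotation.  The
  geometry is frozen in code; the matching claim depends only on the
  half-turn relationship, not the exact proportions.
- `make_known_deformation_pair()` — self-consistency data generated by the
  model itself (small seeded momenta, halved on degeneracy); it tests
  recovery, not model misspecification.
- `make_censored_slab()` — a 6 mm two-region slab whose measured half is
  deformed by a ground-truth shot with momenta supported on that half.
  The deformation is spatially varying within regions, so it cannot be
  absorbed by per-region law scales, and the support cut falls between
  section planes so the censor's preferred transition width
  ($\lambda \approx 0.32$ mm) is thin relative to the section spacing
  (1 mm).
- `make_striped_gene_field()` — Poisson detections with a left/right
  intensity contrast versus a matched-total uniform decoy.
- `make_curvilinear_arc()` — mass concentrated on a thin arc with a
  feature gradient along it, the regime where optimized placement beats
  lattices.
- `make_section_stack()` — an asymmetric C-shaped footprint with small
  per-section jitter.

All generators are pure functions of their arguments.  What passing tests
on these phantoms do **not** show: robustness to segmentation or
cell-typing error, to anisotropic section distortion, to slice dropout
(deliberately not modeled as censoring — dropped slices are simply absent
from the data), or to the feature-space sizes (hundreds of genes, tens of
cell types) of real experiments.

## Problem sizes and runtime posture

The shipped tests run the matchers at 27–64 particles with 5–8 RK4 steps
and 60–150 optimizer iterations, the resampler at a few hundred particles,
and the rotation sweep at ~1k particles per measure — sizes chosen so the
full suite exercises every code path on one CPU in minutes.  The
quadratic kernel sums and the $O(n^2)$ per-step shooting cost mean real
atlas-scale problems (10⁵–10⁶ particles) require the truncated kernel
mode, coarse-scale resampling first, and patience; the package is a
reference implementation at desk scale, not a GPU production code.

## Known limitations

- Kernel sums are dense $O(nm)$ matrices; the truncation option zeroes
  entries but does not exploit sparsity structurally.
- Outer-loop momenta gradients are forward differences, so matching cost
  grows linearly in particle count beyond the $O(n^2)$ objective itself.
- Label volumes are read from NIfTI files or in-memory arrays; other
  labeled-volume dialects must be converted upstream.
- The learned censor is a coordinate classifier; it does not see image
  intensity or local density, only positions.
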