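---
title: "Methods: fODF estimation with deep constrained spherical deconvolution"
author: "dcsd package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fODF estimation with deep constrained spherical deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diffusion-weighted MRI (DWI) measures water diffusion along many gradient
directions on one b-value shell. In white matter the per-voxel fiber
orientation distribution function (fODF) — a nonnegative, antipodally
symmetric function on the sphere whose lobes point along the axon bundles
crossing the voxel — is conventionally estimated by constrained spherical
deconvolution (CSD): the measured signal is modelled as the spherical
convolution of the fODF with an axially symmetric single-fiber response,
and inverted under a nonnegativity constraint. CSD estimates, however, are
not reproducible across repeated acquisitions of the same anatomy: noise,
scanner drift, intensity bias and gradient-frame differences all propagate
into the fODF.

This package implements a learning-based estimator addressing exactly that
weakness: a small 3×3×3-patch convolutional network that maps the
spherical-harmonic (SH) representation of the signal to fODF SH
coefficients, trained with a two-term loss — a conventional fitting term
against full-direction CSD "silver standard" labels, and a scan/rescan
reproducibility term that directly penalizes disagreement between the
network's outputs for corresponding voxels of two registered acquisitions
of the same anatomy. A gradient-direction-dropout augmentation teaches the
network to produce full-direction-quality fODFs from sparser acquisitions.
Because the real test–retest cohorts such methods are developed on are
access-restricted, the package carries a synthetic scan/rescan phantom
generator with analytic ground truth, and every claim the package makes is
validated on those phantoms.

## Signal representation

All spherical functions use a real, antipodally symmetric SH basis: even
orders $k \le L$ only, $(L+1)(L+2)/2$ basis functions (45 at the default
$L=8$), ordered by increasing $k$ and, within an order, by degree
$m=-k,\dots,k$. The normalization is orthonormal ("real-sym-orthonormal"):
with $\bar P_k^m$ the fully normalized associated Legendre function
*without* the Condon–Shortley phase,

$$
Y_{k}^{m}(\theta,\phi)=
\begin{cases}
\sqrt{2}\,\bar P_k^{|m|}(\cos\theta)\sin(|m|\phi) & m<0\\
\bar P_k^{0}(\cos\theta) & m=0\\
\sqrt{2}\,\bar P_k^{m}(\cos\theta)\cos(m\phi) & m>0.
\end{cases}
$$

Published real-SH conventions differ by $\sqrt2$ factors between variants;
all quantities in this package (fits, convolution scales, the ACC metric,
CSD) are self-consistent within this one documented convention, which is
what every property actually requires. Signals are divided by the voxel's
mean b=0 value before fitting (standard single-shell practice), and the
"signal ODF" — the least-squares SH fit of the normalized amplitudes — is
the unified model input. The unpenalized fit requires at least 45
directions and a design-matrix condition number below $10^6$; a
Laplace–Beltrami-weighted ridge (`lbWeight`, penalty $(k(k+1))^2$ per
order) is available for sparser direction sets and defaults to 0.

## The synthetic scan/rescan phantom

`makePhantom()` builds a deterministic two-bundle digital phantom: one
coherent bundle bending gently about the x axis, a second along y, and a
90° crossing where they overlap; orientations vary smoothly within bundles
(neighbor angular change well under 15°) and the fiber-bearing voxels form
the white-matter mask. Signals follow the standard multi-tensor forward
model at one shell,
$S(g) = s_0\left[\sum_i f_i e^{-b\,g^\top D_i g} + f_{\mathrm{iso}}
e^{-b D_{\mathrm{iso}}}\right]$, with prolate tensors
$\lambda = (1.7, 0.2, 0.2)\times10^{-3}\,\mathrm{mm^2/s}$ and a free-water
compartment $D_{\mathrm{iso}} = 3.0\times10^{-3}$ — textbook adult
white-matter values. Defaults: $16^3$ grid, 96 electrostatically uniform
directions at $b = 2000\,\mathrm{s/mm^2}$, 3 b=0 volumes; single-fiber
voxels carry fiber fraction 0.7, crossing voxels 0.4 + 0.4.

The ground-truth fODF of a voxel is a mixture of antipodally symmetric
Watson-like lobes $\propto e^{\kappa(d\cdot\mu)^2}$ (default $\kappa=50$,
a lobe width typical of coherent white matter) plus a uniform component
carrying the isotropic fraction. Two numerical choices matter here:

* **Nonnegativity.** An order-8 truncation of the $\kappa=50$ Watson lobe
  rings to about $-11\%$ of its peak — no nonnegative density has those
  coefficients. The canonical lobe is therefore the *nonnegative
  band-limited approximation* of the Watson kernel, computed by
  alternating projections between the band-limited subspace and the
  nonnegative cone on a 1448-point quadrature grid, plus the minimal
  isotropic floor covering residual between-grid negativity. Alternatives
  that keep the raw truncation and only lift the order-0 term were
  rejected: the angular part of such a "ground truth" is unrealizable by
  any nonnegative density, and recovery scores against it measure the
  ringing, not the estimator.
* **Rotation.** Per-voxel lobes are produced from the canonical zonal
  profile by the SH addition theorem, so peaks sit exactly on the
  configured fiber directions and per-order energies are exactly
  rotation-invariant; the tests verify this route against an independent
  per-voxel dense-quadrature projection.

A rescan differs from its scan by (i) independent Rician noise
(magnitude-MR model, $\sqrt{(S+\epsilon_1)^2+\epsilon_2^2}$,
$\epsilon\sim N(0, s_0/\mathrm{SNR})$), (ii) a multiplicative low-frequency
intensity bias field, and (iii) a small rigid rotation of the gradient
frame. Defaults — scan SNR 30, rescan SNR 25, 5% bias, 3° rotation — are a
mild, realistic variability regime; both volumes share the phantom
geometry, mirroring pairwise-registered test–retest data. These defaults
are stipulated, not fitted: real intersite effect sizes are not publicly
characterized for the restricted cohorts this generator stands in for.

What the phantom deliberately does *not* model: eddy/motion/susceptibility
artifacts, multi-shell acquisitions, spatially varying response functions,
inter-subject anatomy, registration error. Tests passing on phantoms
therefore validate the algorithms and their orderings under controlled
variability, not clinical performance.

## Constrained spherical deconvolution

The response function is estimated from the phantom's analytically known
single-fiber voxels (no FA thresholding needed): each voxel's normalized
signal is reoriented so the principal axis of a log-linear tensor fit
(negative amplitudes clamped at $10^{-6} s_0$ before the log) aligns with
+z, the pooled samples are fit with the m=0 even-order terms, and the
resulting zonal coefficients $r_k$ define the kernel. Forward convolution
scales each coefficient by $r_k\sqrt{4\pi/(2k+1)}$ (the spherical
convolution theorem for zonal kernels under an orthonormal basis).

`csdFit()` is the classical hard-threshold iterative scheme: initialize
with the unconstrained deconvolution truncated at order 4 (the standard
bootstrap — it stabilizes the first active set); at each iteration, the
amplitudes on a fixed 724-point symmetric constraint sphere falling below
$\tau\times$(mean initial amplitude) form the active set, penalized with
weight $\lambda$ in a regularized least-squares solve; stop when the
active set repeats or after `nIter` iterations. Defaults
$\tau = 0.1, \lambda = 1, 50$ iterations — the canonical values of the
single-shell single-tissue variant. Numerical parity with any specific
library release is a non-goal; self-consistency and recovery are what the
tests assert.

One honest caveat, discovered by measurement: with the canonical
$\tau/\lambda$ the converged fODF is *near*-nonnegative — residual
constraint-sphere negativity is typically under 1% of the maximum but
reaches about 2% on 90°-crossing voxels. Raising $\lambda$ (or finishing
with a graduated hard penalty) pushes this toward $-1.2\%$ at best while
measurably degrading recovery accuracy against the analytic ground truth
(mean ACC drops from 0.950 to about 0.935). The package keeps the
canonical defaults and documents the soft bound (within $-3\%$ of max per
voxel, enforced in the tests) rather than trading recovery accuracy for a
cosmetic constraint.

fODF peaks are extracted by local maxima on the 724-point grid, refined by
a deterministic shrinking-cap search (cap radii 6°→0.15°), thresholded at
25% of the global maximum and merged below 25° separation — deterministic
and accurate to well under 1° against a brute-force dense-grid argmax.

## The estimator

**Patch CNN.** Input: the 3×3×3 neighborhood of a voxel, 45 SH channels.
conv1 (1×1×1, 45 filters) → conv2 (3×3×3, padding 1, 45 filters) → conv3
(3×3×3, valid, 45 filters), then two dense layers (45→200→45) predicting
the 45 fODF coefficients of the *center* voxel. Batch normalization sits
after each hidden affine, before its ReLU; the output layer is linear
(coefficients are signed). A residual shortcut connects the conv1
activation to the conv3 output; conv3 collapses the patch to 1×1×1 while
conv1 preserves 3×3×3, so the shortcut takes the conv1 activation's center
voxel (channel counts match and the center is the prediction target); a
spatial-average alternative is available via `shortcut = "avgpool"`. The
hidden dense width (200) mirrors the baseline MLP's penultimate layer; the
architecture literature this design follows fixes the convolutional stack
but not the head width.

**Voxel MLP baseline.** 45 → 400 → 45 → 200 → 45, ReLU on hidden layers,
linear output, no spatial context.

**Loss.** For a labeled batch and a paired scan/rescan batch forwarded
through the *same* network,

$$
\mathcal{L} = \alpha\,\frac1N\sum_i\sum_{k,m}
\left[(c_k^m)_{\mathrm{true},i}-(c_k^m)_{\mathrm{pred},i}\right]^2
+ \beta\,\frac1N\sum_i\sum_{k,m}
\left[(c_k^m)_{u,i}-(c_k^m)_{v,i}\right]^2 ,
$$

where $u_i, v_i$ are the network outputs for the same voxel location in
the two volumes of a pair. The second term has expectation 0 for a
perfectly reproducible estimator; $\beta = 0$ when no paired data
participate. Defaults $\alpha = \beta = 1$ (the source method states no
values; both are config-exposed). Gradients flow through both the $u$ and
$v$ branches — the term is symmetric and there is no reason to
stop-gradient either side. Pairs are matched per voxel within the batch,
not averaged per volume. At inference the model consumes single patches
only; no rescan is ever needed after training.

**Training protocol.** The engine is a compact native implementation of
the required pieces (affine/conv-as-matrix layers, batch normalization
with running statistics, hand-derived backpropagation verified against
numerical gradients, Adam); the models are small enough that BLAS matrix
products on one CPU core are entirely adequate. The reference protocol
(`trainStudyModel()`) uses Adam at learning rate $3\times10^{-3}$, batch
64, up to 400 steps, with model selection on validation mean ACC every 50
steps (patience 5). The learning rate was chosen by a small sweep of
validation ACC on the reference study; batch 64 (rather than a larger
batch) is proportionate to the ~500 interior training voxels of a $16^3$
phantom. Training patches are restricted to voxels whose full 3×3×3
neighborhood lies inside the volume; inference reflect-pads the border.
Everything is bit-reproducible given the seeds, which are derived
hierarchically from one master seed so components (noise, sampling,
initialization) can be varied independently.

**Augmentation.** With probability proportional to the number of supplied
input fields, a labeled sample's input is drawn from one of the
direction-dropout copies: a uniformly random subset of at least 45
directions (the order-8 basis size; b=0 volumes are never dropped) is
accepted only if it passes a coverage check, and the signal SH is refit
from the retained directions only. The label is always the full-direction
CSD field, bit-identical across copies. The coverage check is the
conjunction of a design-matrix condition-number bound and a maximum
empty-spherical-cap bound (30°, on a 724-point probe grid after antipodal
identification). "Well distributed" is not defined by the source method;
these two statistics are cheap, deterministic and directly tied to fit
stability. The condition-number default is $10^3$: measured on random
45-of-96 subsets of a uniform scheme, condition numbers range over
roughly 25–500 (a *designed* 45-direction scheme sits near 5), so a
threshold of 10 — natural for designed schemes — would reject essentially
every random dropout subset and make the augmentation undefined; $10^3$
accepts typical subsets while the cap-gap bound still rejects
hemisphere-clustered degenerate sets. Rejected subsets are resampled (up
to 100 attempts), not repaired.

## Evaluation

The angular correlation coefficient of two coefficient vectors excludes
the order-0 term:

$$
\mathrm{ACC}(u,v)=\frac{\sum_{k\ge1}\sum_m u_k^m v_k^m}
{\left(\sum_{k\ge1}\sum_m |u_k^m|^2\right)^{1/2}
\left(\sum_{k\ge1}\sum_m |v_k^m|^2\right)^{1/2}} \in [-1,1],
$$

i.e. the cosine similarity of the anisotropic coefficient blocks (the
conjugate in the complex-basis definition is the identity here — the basis
is real; this is documented, not configurable). A voxel with zero energy
above order 0 in either argument has an *undefined* ACC (0/0): `acc()`
raises an error and `accMap()` records `NA` and counts it, rather than
silently reporting 0, which would bias white-matter means. Map summaries
are NA-excluding mean/SD with counts. The order-0 coefficient map is
exposed as `zerothCoeffMap()` (alias `mdMap()` for the name sometimes used
in the harmonization literature — note it is not a diffusivity in physical
units). Paired comparisons use a two-sided Wilcoxon signed-rank test with
zero differences dropped and mid-ranks for ties; the null is exact
(computed by convolution over signed mid-ranks, valid under ties) for up
to 25 effective pairs and a continuity-corrected normal approximation
above.

## The reference study and what it shows

`referenceStudy()` fixes the desk-scale experiment: $16^3$ phantom, the
96-direction $b=2000$ scheme, scan/rescan at the default perturbation,
full-direction CSD of the scan as silver standard and training labels, and
a deterministic 70/15/15 train/validation/test split of interior WM
voxels. On it, the package's acceptance suite verifies (3 fixed seeds):

* training with $\beta=1$ yields scan/rescan prediction consistency at
  least as high as $\beta=0$ — the reproducibility term does what it is
  for (measured at seed 1: mean scan/rescan ACC 0.987 → 0.994, i.e. the
  residual disagreement roughly halves);
* the trained patch model tracks the full-direction silver standard on
  held-out voxels (mean ACC well above 0.85);
* noiseless CSD recovers the analytic ground truth (mean ACC ≥ 0.95,
  single-fiber peaks within 2°, crossing peaks within 5°).

Two orderings reported on real multi-subject cohorts do **not** transfer
to this synthetic setting, and the corresponding acceptance checks are
expected to fail here; the package reports them honestly rather than
redefining them:

* *Patch CNN vs voxel MLP accuracy.* CSD is a voxelwise deterministic map
  of the voxel's signal SH, and on a phantom the silver-standard label is
  exactly that map applied to the very input the models see. A voxelwise
  MLP can therefore approximate its own training target almost perfectly
  (measured ≈ 0.998 mean ACC), while spatial context gives the patch model
  nothing to exploit and slows its optimization (≈ 0.92–0.96 at the same
  budget). The real-data ordering rests on inter-subject variability,
  registration error and preprocessing residuals that make pure
  voxelwise mapping harder — features the phantom deliberately lacks.
* *Augmented model vs reduced-direction CSD.* At SNR 30, CSD refit from 45
  of 96 directions of the *same* noisy scan agrees with the full-direction
  CSD of that scan at ≈ 0.996 mean ACC (shared noise, strongly regularized
  inversion): there is essentially no degradation for the learned model to
  beat, and a desk-scale model (≈ 0.85–0.95 from 45-direction inputs)
  cannot out-agree a reconstruction that shares its target's noise. The
  separation seen on real data presupposes acquisition conditions in which
  sparse CSD visibly degrades.

Both analyses are reproducible from the exported study functions
(`studyAccuracy()`, `studyConsistency()`, `dropoutComparison()`).

## Problem sizes

All shipped experiments run on one CPU core: $16^3$ phantoms
(≈ 1000 WM voxels), 96-direction schemes, 724-point constraint spheres,
and 400-step trainings (≈ 30 s for the accuracy-only patch model, ≈ 2 min
with the paired term; the voxel MLP trains in seconds). These sizes were
chosen so that the full validation suite — phantom generation, CSD label
fits, nine model trainings across three seeds, and all evaluations —
completes comfortably in a coffee-break on a laptop while leaving every
ordering measurable.

## Known limitations

* Single shell, single tissue; multi-shell multi-tissue deconvolution is
  out of scope.
* Voxel-space processing only: gradient directions are not reoriented by
  the NIfTI affine (phantom outputs use identity affines).
* The CSD nonnegativity constraint is soft (see above).
* Phantom realism limits: see the generator section — conclusions about
  orderings on real cohorts require real cohorts.
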