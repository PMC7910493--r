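---
title: "Diffusion histology imaging with dhikit: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion histology imaging with dhikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhikit)
```

## The signal model

dhikit implements diffusion basis spectrum imaging (DBSI), which writes a
voxel's normalized diffusion-weighted signal as a sum of discrete
cylindrically symmetric anisotropic tensors plus a continuous spectrum of
isotropic tensors:

$$
\frac{S_k}{S_0} \;=\; \sum_{i=1}^{N_{\mathrm{aniso}}}
  f_i\, e^{-b_k \lambda_{\perp i}}\,
  e^{-b_k(\lambda_{\parallel i}-\lambda_{\perp i})\cos^2\phi_{ik}}
\;+\; \int_a^b f(D)\, e^{-b_k D}\, dD ,
$$

where $b_k$ is the $k$-th diffusion weighting, $\phi_{ik}$ the angle
between the $k$-th gradient direction and the $i$-th tensor axis,
$\lambda_{\parallel}\ge\lambda_{\perp}$ the axial and radial diffusivities
of a cylindrically symmetric tensor, and $f(D)$ the signal fraction at
isotropic diffusivity $D$.  Internally all diffusivities are in
µm²/ms and b-values are converted to ms/µm² (b[s/mm²]/1000), so
$e^{-bD}$ is dimensionally consistent.  The spectrum is discretized as
non-negative weights on a grid whose weights carry the measure, which is
exactly the representation the non-negative least-squares (NNLS) inverse
uses.

The spectrum is cut into the bands used for tumor histopathology:
highly restricted ($0 \le D \le 0.2$, associated with lymphocytes),
restricted ($0.2 < D \le 0.8$, dense tumor cellularity), hindered
($0.8 < D \le 2$, necrosis/edema) and free water ($D > 2$, all µm²/ms).
Band edges are closed above: weight exactly at $D=0.8$ is restricted, at
$D=2.0$ hindered.  The default grid (31 points, 0.1 spacing on
$[0, 3]$) places every edge exactly on a grid point; the upper limit 3.0
leaves headroom above the hindered band for a free-water band.

## Encoding schemes

`generateScheme()` places diffusion directions quasi-uniformly by a
golden-spiral lattice and assigns non-zero b-values uniformly spaced on
$(0, b_{\max}]$ in a seed-reproducible random pairing.  A multi-b design
is the default because a single shell cannot constrain an isotropic
*spectrum*: all mono-exponential decays are indistinguishable from one
b-value.  The reference acquisition in this field — and the default in
the phantoms — uses 99 directions with maximum $b = 3000$ s/mm² plus one
unweighted acquisition.  How the 99 b-values are distributed below the
maximum is not standardized, so the assignment is configurable
(`bMin`, or load a measured scheme via `loadScheme()`).

## The inverse problem

`fitVoxel()` solves the decomposition in four stages:

1. **Full-basis NNLS.**  A linear basis of ~100 candidate orientations
   (cylinders at the initial diffusivities $\lambda_\parallel = 1.5$,
   $\lambda_\perp = 0.3$ µm²/ms, typical for fixed tissue) plus the
   isotropic grid is fit by NNLS with a Tikhonov ridge on the spectrum
   block ($0.01\,\sigma_{\max}$ of the design).  NNLS on exponential
   bases is severely ill-posed; without the ridge the anisotropic block
   absorbs isotropic signal wholesale.
2. **Orientation selection.**  Anisotropic weights are clustered over
   axes within 15° (antipodally symmetric; the cluster axis is the
   weight-averaged member axis, which resolves orientation below the
   grid spacing), clusters below 2% of the total weight are dropped, and
   at most three survive.  Clustering happens *before* thresholding
   because a true fiber's weight is split across neighboring grid
   orientations — thresholding raw per-orientation weights silently
   deletes moderate fibers.  The reduced basis is refit and re-pruned
   until stable.
3. **Diffusivity refinement.**  A candidate grid over
   $(\lambda_\parallel, \lambda_\perp/\lambda_\parallel)$ is scored on a
   neighborhood orientation basis (grid directions within 30° of a kept
   axis, so the axis estimate can move with the candidate).  Refined
   diffusivities are adopted only when they improve the residual by at
   least 5% (`refineTol`): at realistic SNR a 1–3% residual gain is
   noise chasing, while a true $\lambda$ mismatch produces a much larger
   drop.  On adoption the full-basis orientation selection is repeated
   with the refined $\lambda$, a second candidate pass plus a short
   Nelder–Mead polish sharpens the values, and the result is kept only
   if it beats the unrefined reduced fit.
4. **Metric derivation.**  Band fractions (normalized, with the fiber
   fraction, to sum to 1), weight-averaged within-band diffusivities,
   the spectrum-weighted isotropic ADC, and mean ADC / mean FA from a
   weighted log-linear single-tensor DTI fit (`fitDTI()`, weights
   $S_k^2$, eigenvalues clipped at zero).  A band with no weight reports
   a diffusivity of 0.  "Mean FA" is the DTI FA: it is listed alongside
   mean ADC in the metric set, and the DTI tensor is the natural source
   for both.

Two numerical choices deserve emphasis.  First, the *reduced-stage*
regularization is noise-adaptive: ridge (weight 0.3) and
second-difference smoothness (weight 1.0) penalties on the spectrum are
scaled by the noise SD estimated from an unregularized reduced fit.  A
fixed penalty smears a noiseless spectrum across band edges, well below
the near-complete band concentration a noiseless single compartment
should show, while no penalty at all leaves the noisy band fractions far
more variable; scaling by the estimated noise gives exact noiseless
recovery and stabilized noisy recovery with one mechanism.  Second, the
anisotropic acceptance threshold default is 0.02 of total weight rather
than a more conservative 0.05: with profile-realistic fiber fractions
(6–40%), a 0.05 cut silently deletes genuine moderate fibers and biases
the fiber fraction downward, while 0.02 keeps them without admitting
spurious fibers in isotropic voxels (the iterative prune step removes
those).  Both are `dbsiConfig()` parameters.

The fitted model's residual never exceeds the isotropic-only fit on the
same voxel (the isotropic basis is a subset of the final basis and NNLS
is convex), outputs are invariant to acquisition order, and
`fitVolume()` is deterministic.

## Synthetic phantoms

No specimen data are distributable, so `dhikit` generates its own study
material at two levels.

**Feature tables** (`sampleFeatureTable()`) draw per-voxel metric
vectors from per-class profiles (`defaultProfiles()`).  The profiles
carry the published group means ± SDs wherever a value was printed
(ADC, DTI-FA, fiber fraction, restricted/hindered/free fractions for
the classes they were reported for); the normal-white-matter ADC
(0.20 µm²/ms) is implied by the published 115% densely-cellular-vs-WM
contrast; every remaining entry is a documented plausible default, and
the entire hemorrhage profile is synthesized (no diffusion statistics
were published for it) and flagged `synthetic`.  The five
signal-fraction metrics are drawn jointly: independent Gaussian
deviations are projected onto the zero-sum subspace
(minimum-variance allocation), so compartment fractions compete for
signal exactly as they do physically, the fraction sum equals the
profile's (≤ 1) total, and the printed marginal means are preserved
exactly.  The cost is mildly shrunk marginal SDs — with only marginal
statistics published, matching means, SDs *and* the sum constraint
simultaneously is impossible, and we prioritize the means, which the
recovery and contrast checks consume.  Non-fraction metrics are
independent truncated normals; metrics whose published mean sits within
~2 SDs of a support boundary (e.g. necrosis ADC 0.68 ± 0.37) acquire an
unavoidable truncation bias of up to ~0.03, which the tests acknowledge
with an absolute 0.05 tolerance.  Only marginals are emulated: the
authors' joint feature distribution (and hence their classifier
accuracy) is *not* reproducible from printed statistics, which is why
the classifier acceptance checks use separately constructed
well-separated classes for accuracy claims and the published profiles
only for end-to-end execution.

**Signal phantoms** (`buildSignalPhantom()`) draw a ground-truth
`VoxelModel` per labeled voxel — one fiber (axis uniform on the sphere;
$\lambda_\parallel$, $\lambda_\perp$ uniform in fixed-tissue ranges of
roughly 0.8–1.4 and 0.2–0.55 µm²/ms by class) plus one representative
diffusivity per isotropic band (uniform within 0.05–0.15, 0.35–0.65,
1.1–1.7 and 2.3–2.7 µm²/ms) — predict the exact signal and add Rician
noise (`addNoise()`, noise SD $1/\mathrm{SNR}$ of the unweighted
signal).  Rician is the correct magnitude-MRI noise model; Gaussian is
available for diagnostics.  Ground truth is retained per voxel so
recovery is scored against the actually drawn composition, not the
profile mean.

## Histology-to-MRI registration

`fitTPS()` solves the standard 2-D thin-plate-spline system with kernel
$U(r) = r^2\log r^2$ ($U(0)=0$).  With zero regularization the spline
interpolates landmarks to machine precision and reproduces any affine
correspondence with exactly zero warping weights; the side conditions
($\sum w_i = 0$, $\sum w_i p_i = 0$) hold by construction.  Coordinates
are pixel centers, origin $(0,0)$, $x$ = column — fixed so exactness is
testable.  `warpImage()` resamples by inverse mapping (the supplied
transform maps output to input coordinates); label masks use nearest
neighbor so no new labels appear, intensities use bilinear.
`transferROIs()` crosses the ~80× resolution gap between 20×
histology and 0.25 mm MRI voxels by forward-mapping every labeled
histology pixel and majority-voting within each MRI voxel; exact ties
are left unlabeled and counted rather than broken arbitrarily.

## The classifier

`trainDNN()` is a fully connected network matching the published
architecture where stated: ten hidden layers, batch normalization with
mini-batch 200, exponential linear units, a softmax head over the six
histology classes, Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$),
cross-entropy loss, and early stopping on validation loss with the
best-validation weights restored.  Width (128), learning rate (10⁻³),
epoch budget (100) and patience (10) were not reported and are package
defaults sized for 12-feature tabular input.  Features are additionally
z-scored with training-set statistics because the metrics span orders
of magnitude.  Training is deterministic given the config seed; the
backward pass (including batch-norm gradients) is verified against
numerical differentiation in the test suite.

Splitting is voxel-wise 8:1:1 (`splitDataset()`; test and validation
each get `round(0.1 N)` rows, stratified splits allocate by largest
remainder so the global sizes are exact).  Voxel-wise splitting follows
the original design but risks specimen-level leakage in real data — a
caveat, not a property the phantoms can exhibit.  `smoteBalance()`
implements SMOTE with $k = 5$ neighbors by default (the method's
canonical default; the study did not state its value): synthetic
minority rows are uniform interpolations toward a random one of the
$k$ nearest same-class neighbors, originals are kept unchanged, and
balancing is only ever applied to training data.

## Evaluation battery

`confusionStats()`, `rocOneVsRest()`, `prOneVsRest()`, `youdenPoint()`,
`bootstrapCI()`, `mannWhitney()` and `groupStats()` cover the study's
statistics.  Choices where conventions differ:

* ROC ties contribute ½, making the trapezoidal AUC exactly the
  Mann–Whitney pair statistic (a property test enforces the identity
  against brute-force pair counting).
* PR curves are summarized by average precision (step interpolation),
  not the trapezoid, which is optimistic between recall levels.
* Youden ties break toward higher specificity, then higher threshold,
  for determinism.
* Bootstrap CIs are percentile CIs from row resampling; degenerate
  resamples (e.g. single-class) are skipped and counted, and more than
  50% degenerate aborts.
* `mannWhitney()` enumerates the exact permutation distribution (with
  midrank ties) for small samples and falls back to the tie- and
  continuity-corrected normal approximation; group SDs support both the
  sample and population conventions (the published cohort ages match the
  population convention).
* Percent differences are reported as integer percent,
  $100(m_1 - m_2)/m_2$.

## Problem sizes and determinism

The shipped checks run at desk scale, chosen to exercise the claims
rather than the hardware: phantom recovery uses 500 voxels per class at
SNR 50 with the 99-direction scheme (~5 minutes on one core); the
classifier sanity check uses 600 voxels per class; bootstrap coverage
uses 200 outer replications of a 2,000-replicate percentile CI at
$n = 200$ (the CI convention in the evaluation itself defaults to the
published 10,000 replicates).  Every stochastic stage takes an explicit
seed, and `runEndToEnd()` records config and artifact hashes in a
manifest so a rerun is bit-identical.

## Known limitations

* Phantom feature tables emulate printed marginals only; joint
  structure, skew and within-specimen correlation are absent, so
  classifier performance on phantoms says nothing quantitative about
  performance on real specimens.
* At SNR 50 the fiber/isotropic split is weakly identified for small
  fibers; pooled recovery MAE for fiber and restricted fractions sits
  near 0.05, with the restricted fraction occasionally above it —
  the spectrum inversion, not the implementation, is the bottleneck.
* Per-voxel $\lambda$ refinement is gated by residual improvement; a
  mismatch too small to clear the gate leaves diffusivities at their
  initialization (band fractions are barely affected).
* Crossing fibers beyond three components, exchange, and
  time-dependent diffusion are out of scope, as are scanner-level
  acquisition effects.
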