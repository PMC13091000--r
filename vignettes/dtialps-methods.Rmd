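---
title: "Methods: the ALPS index, its automated computation, and the simulation framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ALPS index, its automated computation, and the simulation framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtialps)
```

## The measurement model

Diffusion along the perivascular space (DTI-ALPS) exploits an anatomical
coincidence at the level of the lateral ventricles: medullary veins — and
the perivascular spaces that sheath them — run along the right–left (x)
axis, perpendicular to both the projection fibers (inferior–superior, z)
and the association fibers (anterior–posterior, y) that surround them.
Water mobility *along* x in these two fiber populations therefore cannot be
explained by the fibers themselves; its excess over the fiber-orthogonal
diffusivities is read as a proxy for perivascular fluid mobility, a
putative index of glymphatic function.  Per hemisphere,

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{x,\mathrm{proj}},\
D_{x,\mathrm{assoc}})}{\mathrm{mean}(D_{y,\mathrm{proj}},\
D_{z,\mathrm{assoc}})}$$

where the four quantities are means of the diagonal tensor components
$D_{xx}$, $D_{yy}$, $D_{zz}$ over spherical ROIs in projection and
association white matter.  A bilateral value is the mean of the two
hemispheres, and is only defined when both are valid.  Two identities
follow directly from the definition and anchor the test suite: the index is
exactly 1 on isotropic tissue regardless of ROI placement, and it is
invariant under any global rescaling of the tensor field.  A
corpus-callosum control — mean $D_{xx}$ in an x-oriented bundle at the same
axial level — reverses the logic: there, x *is* the fiber axis, so
perivascular effects should not raise it, which makes it a negative control
for group analyses.

## From raw diffusion data to the index

`fitTensorLogLinear()` estimates the tensor per voxel by unweighted
log-linear least squares, $\ln S_i = \ln S_0 - b_i\, g_i^\top D g_i$,
solved in one QR factorization for all voxels.  The choice is deliberate:
it is exactly invertible on noiseless signals (the suite checks recovery of
random SPD tensors to $10^{-10}$), and unbiased under additive Gaussian
noise on $\ln S$.  No eigenvalue clamping is applied; voxels with
non-positive or non-finite signals are flagged invalid and excluded rather
than repaired, so downstream statistics always know which voxels to trust.

Because the index is defined in anatomical axes, volumes are first brought
to a canonical +x right–left / +y anterior–posterior / +z inferior–superior
grid.  `reorientToCanonical()` restricts itself to axis permutations and
sign flips derived from the affine, rotating the tensor components with the
signed permutation ($D'_{ab} = s_a s_b D_{p(a)p(b)}$); affines oblique
beyond tolerance trigger a warning and the nearest-axis permutation.  Full
oblique resampling is intentionally out of scope — it would interpolate
tensors, and every supported input (phantoms, axis-aligned clinical
exports) is axis-aligned to begin with.

### Automated ROI placement

`placeRoisAuto()` reproduces the manual placement rule as a deterministic
classifier.  Within an axial slab at ventricle level, voxels with
FA ≥ `fa_min` are assigned by their principal direction $e_1$: within
`theta_class` of ẑ → projection candidates; within `theta_class` of ŷ →
association candidates; and any voxel whose $e_1$ lies within
`90° − theta_exclude_x` of x̂ is excluded from both classes, implementing
"avoid fibers crossing along the perivascular direction".  Per hemisphere
(mid-sagittal split) the centroid of the largest 26-connected candidate
cluster becomes a spherical ROI.  Defaults — `theta_class` 30°,
`theta_exclude_x` 30°, `fa_min` 0.15, radius 5 mm — classify the phantom
bundles unambiguously; all are configurable, and the radius is a documented
design choice rather than a literature constant (published descriptions of
the spherical ROIs do not state one).  The aggregation statistic over ROI
voxels is the arithmetic mean (median available), likewise a documented
choice.  The $e_1$ sign is fixed (first nonzero component nonnegative) so
that dot-product thresholds are deterministic; classification uses
$|e_1 \cdot \hat a|$, so results are stable under eigenvector sign and
repeated-eigenvalue ties.

## The digital phantom

`buildTensorPhantom()` constructs the geometry the index presumes:
inferior–superior projection columns, anterior–posterior association slabs,
an x-oriented callosal bundle near the midline, a CSF-like ventricle block,
and an isotropic background.  Inside the periventricular slab, $D_{xx}$ of
projection and association voxels is multiplied by a perivascular gain $k$,
so the ground-truth index of the slab is exactly $k$ — the phantom turns an
abstract ratio into a recoverable parameter.  Defaults use a 40 × 48 × 28
grid of 2 mm voxels, bundle eigenvalues 1.4 × 10⁻³ / 0.4 × 10⁻³ mm²/s
(FA ≈ 0.63), and a 12 mm slab, thick enough that a default 5 mm ROI sphere
centered in it never samples unenhanced tissue.  The enhanced $D_{xx}$
stays below the axial eigenvalue for $k \le 3$, so the gain never reorients
the bundles.

`phantomToDwi()` generates the single-tensor signal
$S_i = s_0 e^{-b_i g_i^\top D g_i}$ over a 30-direction b = 1000 s/mm²
Fibonacci-hemisphere scheme plus one b = 0 volume.  Additive Gaussian noise
is the default — it keeps the log-linear fit's error analysis clean —
with Rician noise available where magnitude-data realism matters.  The
recovery suite demands $|ALPS - k| < 0.01$ noiseless and $< 0.05$ at
SNR 30 for $k \in \{1.2, 1.5, 1.8\}$; in practice the noiseless path is
exact to machine precision and SNR 30 errors run below 0.03, including a
small positive bias from the log transform of noisy signals.

## The simulated cohort

`simulateCohort()` is the generative mirror of the model fitted downstream:

$$y_{ij} = \beta_0 + \beta_g G_i + \beta_a t_{ij} + \beta_{ga} G_i t_{ij}
+ \beta_s S_i + u_{0i} + u_{1i} t_{ij} + \varepsilon_{ij}$$

with $t$ age centered at the sample mean, participant random intercepts and
age slopes, and Gaussian residuals.  Defaults encode the study conditions
the analyses assume: 83 controls and 85 deletion carriers, 1–3 scans each,
baseline ages uniform on 5–35 years, ~5-year intervisit intervals (visits
that would exceed age 35 are dropped), a group effect of −0.05, and within
the carrier group a binary positive-psychotic-symptom label with its own
age interaction (−0.01/yr), mirroring the stratified analysis.  Left/right
columns are the latent bilateral value plus independent N(0, 0.02²)
hemispheric offsets, so per-hemisphere filtering and bilateral averaging
are both exercised.  Family IDs are shared with probability 0.1 so the
family-intercept sensitivity model has realistic (mostly singleton)
nesting.

The variance components are the one place the generator could not be read
off a published table, since variance components of the fitted models are
not reported.  They were fixed once, by design: intercept SD 0.13 and
residual SD 0.06 make the group-coefficient standard error ≈ 0.02,
matching the width of the reported 95% CI (−0.10 to −0.01), and slope SD
0.01/yr is large enough that the random slope is identifiable from 1–3
scans per participant.  Under these conditions the suite checks that the
null group × age interaction rejects at ≈ 5% (500 replicates, ±2%) and
that the Wald 95% CI covers β_g = −0.05 in ≈ 95% of 200 replicates (±3%).

## Model fitting and inference

`fitTrajectoryLmm()` fits the REML mixed model with `lme4`, with two
deliberate departures from its defaults.  First, the
observations-versus-random-effects count heuristics are disabled: with one
to three scans per participant, $2n$ random effects always exceed the scan
count, yet the covariance penalty keeps the model identified — the honest
signal is the singularity of the fitted covariance, not the count.  Second,
singularity (any random-effect variance < 10⁻⁸, or `isSingular`) or
non-convergence triggers a refit with a random intercept only, flagged
`model_used = "fallback"` — a defined, observable ladder instead of a
warning the user may miss.  Fixed-effect inference is Wald-z
(CI = β ± 1.96 SE, two-sided normal p), matching the β/CI/p reporting style
of the motivating analyses; Satterthwaite corrections are out of scope.
The control group (or symptom-negative subgroup) is always the reference
level, and age is re-centered on the analysis sample after QC, so the group
coefficient is the difference at the sample's mean age.

Quality control mirrors the published rule: per hemisphere, values outside
[Q1 − 1.5 IQR, Q3 + 1.5 IQR] — quartiles by linear interpolation of order
statistics (type 7), fences computed independently per group in a single
pass — are removed; a scan keeps a bilateral value only if both hemispheres
survive.  Quartile conventions shift removals at small n, hence the
explicit choice.  Groups with fewer than 4 finite values pass through with
a warning rather than being filtered on meaningless quartiles.

2×2 group comparisons use a deterministic rule recovered from the published
table: minimum expected cell count < 5 → two-sided Fisher exact test,
otherwise Yates-corrected χ².  Under this rule the package reproduces seven
of the printed clinical p-values to three decimals from counts alone (the
suite enumerates the Fisher null by hand as an independent oracle).
Multiplicity over the left/right/bilateral model family is handled by
Benjamini–Hochberg FDR at q < 0.05; the family composition is configurable
because the published analysis defers its exact definition to supplementary
material.

## The E/I regression and its calibration

`simulateMrs()` draws a cross-sectional subset (default 39 carriers, one
scan each — the latest) and generates Glx/GABA ratios as
$r = 19.4 - 11.02 \cdot \mathrm{ALPS} + \varepsilon$.  The noise SD is
calibrated by the closed form
$R^2 = s^2 v / (s^2 v + \sigma^2)$
(v = sample ALPS variance of the subset) to a target of 0.25, the variance
share reported for the association.  One nuance is worth stating: the raw
OLS $R^2$ of the fitted model (ALPS + age + sex) carries the usual
finite-sample optimism of roughly $k/n \approx 0.08$ at $n \approx 38$,
so its mean over seeds sits near 0.29 — within the ±0.05 acceptance band
around the target but above it, a property of the estimator rather than a
calibration error.  With the noise switched off the regression recovers the
slope −11.02 and $R^2 = 1$ exactly.

## Numerical choices and degenerate inputs

* FA is computed from rotational invariants (trace and Frobenius norm), so
  no per-voxel eigendecomposition is needed for candidate masks;
  eigenvectors are computed only where placement requires them.
* Connected components use 26-connectivity; a class/side whose largest
  cluster is smaller than `min_cluster_voxels` is an error naming the side
  and class, signalling data unsuitable for automated placement.
* ROI membership is "voxel center within radius, distances in mm through
  the affine"; a sphere with no valid voxels is an error, not a silent NA.
* A non-positive ALPS denominator invalidates the hemisphere and flags the
  measurement; the bilateral value is withheld unless both sides are valid.
* Simulation seeds are explicit in every generator; identical configuration
  and seed reproduce pipeline CSV outputs byte for byte.

## Problem sizes in the shipped test suite

The suite runs the full phantom grid (40 × 48 × 28, 31 volumes) for the
recovery checks, a 24 × 28 × 16 phantom for unit tests, 500 null and 200
effect replicates of the 168-participant cohort for mixed-model
calibration, and 200 seeds of the n ≈ 39 MRS subset — sizes chosen so a
complete run stays around two minutes on one core while keeping Monte
Carlo error well inside each acceptance band.

## Known limitations

The phantom is geometric, not anatomical: bundles are axis-aligned boxes,
there is no crossing-fiber partial volume, no eddy/motion artefact, no
susceptibility distortion, and no multi-shell acquisition.  Passing the
recovery suite therefore demonstrates correctness of the computation, not
robustness to the full failure modes of clinical diffusion data.  The
cohort generator draws ages uniformly and assumes the mixed model's own
covariance structure, so model-misspecification behaviour (e.g. non-linear
trajectories) is out of its reach.  Canonicalization handles axis-aligned
affines only, and the automated placement realizes the "atlas-based"
pipeline as principal-direction classification within a caller-supplied
periventricular slab — an atlas-derived mask can define that slab, but no
atlas is bundled.
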