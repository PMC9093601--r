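---
title: "Pseudo-atlas DTI tractography: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-atlas DTI tractography: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudotract)
```

## The problem

Quantifying white matter microstructure from diffusion-weighted MRI
requires isolating named tracts before averaging tensor metrics over them.
Two families of approaches exist: registering a population atlas of labeled
tracts onto each subject, and tractography constrained by regions of
interest (ROIs). This package implements a *cohort-specific pseudo-atlas*
workflow — one representative subject's FA map carries a set of declarative
AND/NOT ROI recipes, which are propagated to every other subject of the
cohort by affine registration and applied to each subject's own whole-brain
streamline set — together with an atlas-label comparator, ventriculomegaly
measurement (Evans' index), radar-style "DTI profiles", and the paired
statistics used to compare the two methods. A synthetic phantom generator
supplies ground truth for every stage, so the whole pipeline is testable
without clinical images.

## Models

### Diffusion tensor

Per voxel the signal follows the Stejskal–Tanner monoexponential model
$S_k = S_0 \exp(-b_k\, g_k^\top D\, g_k)$ with $D$ a symmetric positive
3×3 tensor (mm²/s). The fit is ordinary (unweighted) log-linear least
squares on $\ln S_k$, solved in a single QR factorization for all voxels;
$\ln S_0$ is the intercept, which makes the fit exact on noise-free input.
The estimator needs at least six non-collinear diffusion directions plus a
$b=0$ measurement; the design-matrix rank is checked up front. Weighted or
nonlinear estimators would differ in noise propagation but not on the
noise-free oracles used in the tests; OLS was chosen for determinism and
auditability. From sorted eigenvalues $\lambda_1 \ge \lambda_2 \ge
\lambda_3$ (computed by a vectorized closed-form solver, cross-checked
against `eigen()`):

* FA $= \sqrt{3/2}\,\lVert\lambda - \bar\lambda\rVert / \lVert\lambda\rVert$
  (defined as 0 for an all-zero tensor rather than NaN),
* MD $= \bar\lambda$, L1 $= \lambda_1$, RD $= (\lambda_2+\lambda_3)/2$
  (the two radial eigenvalues are reported as one quantity).

Negative eigenvalues — a magnitude-noise artefact — are clamped to zero and
counted.

### Tractography

Deterministic streamline integration follows the principal eigenvector
field with trilinear interpolation; the eight neighbouring eigenvectors are
sign-aligned to the incoming direction before averaging (the tensor field
is an axis field, not a vector field). Integration is bidirectional from
every seed; a streamline half stops when interpolated FA falls below
`fa_threshold`, the per-step turning angle exceeds `angle_threshold`, it
leaves the volume, or it reaches `max_length`. Defaults: step = 0.5 × voxel
size, FA threshold 0.2, angle threshold 45°, one seed per suprathreshold
voxel at the voxel centre, minimum length 10 mm. These mirror common
deterministic-tractography practice; the source method's exact settings are
not published, so runs record all parameters in provenance.

**Integrator.** The default integrator is classical RK4, with fixed-step
Euler available as an option. At 2.7 mm voxels and half-voxel steps, Euler
on a curved bundle drifts radially outward by $h^2/2R$ per step — about
2.6 mm over a full callosal arch — which expels surface-seeded streamlines
from the bundle before they reach anterior gates. RK4 removes the drift for
four field evaluations per step; with it, step-halving changes phantom
bundle lengths by well under 2%.

### ROI recipes and gate logic

Tract recipes are declarative YAML: per tract a laterality and an ordered
list of gates, each with a polarity (AND/NOT), a slice plane, and a
landmark-relative placement (a fraction of a named structure's
anterior–posterior extent, a slab at a structure edge or centre, the
midline plane, or parasagittal regions lateral to a structure). Placements
resolve to voxel masks against any reference geometry supplying the named
structure masks; nothing is a hard-coded slice index. Anterior–posterior is
world +y (RAS+). Fractions are measured on the structure's axis-aligned
bounding extent; measuring along the callosal arc instead would shift the
genu/body boundary slightly and is noted as an alternative. For bilateral
tracts, AND gates are restricted to the corresponding hemisphere while NOT
gates stay global. A streamline is kept iff some vertex lies in every AND
mask and none lies in any NOT mask; with steps at most half a voxel,
vertex-based membership cannot tunnel through a one-voxel slab. Selection
is verified against a brute-force set-logic oracle in the tests.

The shipped recipe file encodes the eight study tracts (gCC, bCC, ATR,
IFO, ILF, PLIC, PTR, UF; the callosal two midline, the rest bilateral,
hence 14 instances per subject). The genu recipe takes the anterior 1/6 of
the callosal extent; the body recipe takes 1/6–3/4, the posterior 1/4
being the splenium, with a full axial exclusion just beneath the body. The
splenium itself is deliberately not a target; accordingly the callosal
fidelity check in the tests evaluates the genu and body recipes jointly
against the callosal bundle.

### Pseudo-atlas propagation and the atlas comparator

Cross-subject ROI transfer is affine: the template FA map is registered to
each subject FA map (12 parameters about the fixed-image centre,
mean-squared-difference cost, 3-level pyramid, deterministic coordinate
pattern search with a fixed step schedule — no stochastic optimizer, so
registration cannot flake tests), and gate masks are propagated
nearest-neighbour. ACPC pre-alignment is a closed-form rigid transform
from three landmarks (AC, PC, a superior midsagittal point): AC maps to
the origin, AC→PC to −y, the midsagittal plane to x = 0.

The comparator consumes any label volume with an id→tract table and
averages each scalar map over each label's (optionally warped) voxels;
labels with no mapped voxels yield missing entries, and partial atlases
are allowed. For phantom studies the package ships a *synthetic mismatched
atlas*: the subject's true bundle masks dilated and shifted, emulating a
group-average atlas that overspills into neighbouring tissue and CSF.

### Evans' index and profiles

Evans' index is the maximal left–right extent of the frontal-horn
compartment of the ventricle mask divided by the maximal internal cranial
width, both maximized over axial slices after ACPC alignment, each voxel
contributing its full pitch. The frontal-horn compartment is automated as
the ventricle voxels anterior to the AC plane — a heuristic standing in
for a rater's slice choice, exact on the phantom by construction. Radar
profiles scale FA ×20 and MD/L1/RD ×10⁴ so all four metrics share one
axis; the scaling is an exact bijection. Along-tract profiles resample
each streamline to `n_nodes` (default 50) equidistant arc-length nodes,
orient all streamlines consistently by endpoint proximity, and average per
node.

### Comparison statistics

Method comparison uses pairwise-deleted per-subject vectors: Pearson r
with its two-sided p, mean difference, and the two-sided paired t-test
(base R `cor.test` / `t.test`; the tests verify both against hand-written
closed forms). The difference is reported as *atlas minus pseudo-atlas*,
so negative FA differences mean the pseudo-atlas method reads higher FA —
the sign convention of the study tables. Confidence ellipses are
chi-square(2) quantile contours of the fitted bivariate normal. No
multiple-testing correction is applied, mirroring the comparison tables;
this is a limitation, not an oversight.

## The phantom: what it emulates, and what it does not

`phantom_spec()` defaults encode the study's acquisition: 2.7 mm isotropic
voxels, 41 diffusion directions at b = 1,000 s/mm² (spherical Fibonacci
spread) plus 5 b0 volumes, Rician magnitude noise
$S' = \sqrt{(S+\epsilon_1)^2+\epsilon_2^2}$ with σ relative to S0 (0.02 in
cohort tests), and per-subject rigid pose jitter emulating non-ACPC-aligned
cohorts. Anatomy: an arching midline callosum-like bundle
(λ = (1.7, 0.3, 0.3)×10⁻³ mm²/s; a thin annulus, radius 5 mm on a 32 mm
arc, proportioned like the callosal sheet so that anterior-fraction gates
behave as they do anatomically), vertical internal-capsule-like bundles
(1.6, 0.35, 0.35) beside paired ellipsoidal CSF ventricles
(3.0×10⁻³ mm²/s isotropic), anterior–posterior fronto-occipital-like
bundles (1.5, 0.4, 0.4), a gray-matter-like isotropic background
(0.9×10⁻³ mm²/s) and an ellipsoidal inner-skull shell. All parameter
values are typical literature magnitudes and were fixed at design time.
Ground truth records the tensor field, every mask, the pose, ACPC
landmarks and analytic per-bundle metrics.

Ventriculomegaly cohorts (`generate_ei_cohort()`) scale the ventricles
across subjects and couple the internal-capsule bundles to the
enlargement: +0.45×10⁻³ mm²/s on λ1 and −0.075×10⁻³ on the radial
eigenvalues per unit enlargement, i.e. the stretch/compression signature
(FA up) with the axial rise dominating so MD also rises — the
qualitative pattern the pipeline is meant to detect. These couplings are
constructions, not measurements; passing tests show the pipeline
*recovers built-in signs*, not that real tissue behaves this way.

The phantom does not model crossing fibres beyond simple overlap, partial
volume, susceptibility or eddy distortions, gyral anatomy, or realistic
atlas registration error; conclusions about real-data robustness beyond
pose/noise/gate logic are out of reach of these tests.

## Numerical choices and problem sizes

* Registration basin: the deterministic pattern search recovers rotations
  up to roughly 30–40°; beyond that it can settle in local minima. The
  high-jitter cohort experiment therefore draws rotations up to 60°, where
  ACPC pre-alignment demonstrably rescues tract generation.
* Near-degenerate tensors (λ1 ≈ λ2 within 1e-7 relative) get no tracking
  direction; principal axes of isotropic voxels are zeroed below FA 0.1 so
  boundary interpolation is not polluted.
* Test problem sizes: single-subject precision tests run on the default
  48³ × 2.7 mm phantom; cohort-level experiments (ACPC effect) run the
  same anatomy at 36³ × 3.6 mm; analytic tracking fields use dedicated
  small grids. Cohorts of 5–6 subjects are enough for the sign and
  success-rate properties being asserted.
* Ties and quantization: Evans' widths are voxel-quantized, so adjacent
  cohort subjects can tie; monotonicity is asserted weakly with a strict
  overall increase.

## Known limitations

Affine (not diffeomorphic) propagation; OLS (not WLS/robust) tensor fit;
vertex-based (not segment-based) gate membership; the frontal-horn
heuristic; single-shell Gaussian-diffusion modelling only. Each is the
minimal faithful choice for the workflow modelled here, and each is
isolated behind a module boundary where a richer implementation could be
substituted.
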