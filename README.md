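# pseudotract

Cohort-specific pseudo-atlas diffusion tensor tractography, with an
atlas-label comparator, for quantifying white matter microstructure in
cohorts where atrophy and ventricular enlargement confound standard
atlas registration — aging, mild cognitive impairment, Alzheimer's
disease, hydrocephalus. Intended for imaging methodologists who need a
transparent, fully testable reimplementation of the workflow rather than
a GUI toolbox.

## The method

Per voxel, diffusion-weighted MRI is modelled by the Stejskal–Tanner
equation *S*ₖ = *S*₀ exp(−*b*ₖ *g*ₖᵀ **D** *g*ₖ) with **D** a symmetric
3×3 tensor, fit by log-linear least squares. From the sorted eigenvalues
λ₁ ≥ λ₂ ≥ λ₃ come the standard metrics FA, MD, L1 = λ₁ and
RD = (λ₂+λ₃)/2. Whole-brain deterministic streamline tractography follows
the principal eigenvector field (RK4 integration, trilinear sign-aligned
interpolation, FA/angle/length termination).

Named tracts are isolated by declarative **AND/NOT ROI recipes** — a
streamline is kept iff it crosses every AND region and no NOT region.
The shipped recipe file encodes eight tracts (gCC, bCC, ATR, IFO, ILF,
PLIC, PTR, UF; 14 instances per subject counting both hemispheres) with
anatomical placement rules (fractions of the callosal extent, slabs at
structure edges, midline exclusions). In the **pseudo-atlas** workflow
one cohort subject is the template: its resolved gates are propagated to
every other subject through an affine FA-to-FA registration
(deterministic multiresolution pattern search), optionally after a rigid
**ACPC alignment** computed in closed form from the anterior/posterior
commissure landmarks. The **atlas comparator** instead averages the
metric maps under a user-supplied (warped) label volume. Downstream:
Evans' index (maximal frontal-horn width over maximal internal cranial
width, axial view), radar "DTI profiles" (FA ×20, diffusivities ×10⁴),
along-tract profiles, and paired method-comparison statistics (Pearson
r, mean difference, paired t).

A digital phantom module generates synthetic DWI cohorts — arching
callosum-like, internal-capsule-like and fronto-occipital-like bundles,
CSF ventricles with graded enlargement, Rician noise, per-subject rigid
pose jitter, 41×b=1000 + 5×b0 acquisitions at 2.7 mm — with complete
ground truth, so every pipeline stage is tested against known answers.

## Worked example

```r
library(pseudotract)

spec <- phantom_spec(noise_sigma = 0.02)          # study-like acquisition
subs <- generate_cohort(spec, 3, seed = 5)        # 3 synthetic subjects
rec  <- load_recipes()[c("gCC", "bCC", "IFO", "PLIC")]

res <- run_pseudo_atlas(subs, rec)                # template = subject 1
res$success_rate
#> [1] 100
subset(res$metrics, side == "both" & subject == "subj01",
       select = c(tract, FA, MD))
#>    tract        FA           MD
#> 19   IFO 0.6641173 0.0007650251
#> 20  PLIC 0.7185441 0.0007736495
#> 21    CC 0.7239253 0.0007799261

atl <- run_atlas_method(subs)                     # mismatched-atlas labels
comparison_table(subset(atl, side == "both",
                        select = c(subject, tract, FA, MD)),
                 subset(res$metrics, side == "both",
                        select = c(subject, tract, FA, MD)))[1:2, ]
#>   tract metric n          r       r_p     mean_diff          t_p insufficient
#> 1    CC     FA 3 -0.8814638 0.3131173 -4.678858e-01 1.644643e-06        FALSE
#> 2    CC     MD 3  0.9771791 0.1362669  8.159913e-05 1.188198e-06        FALSE

subject_evans_index(subs[[1]])
#> Evans' index: 0.2973 (frontal horns 32.4 mm / cranial vault 109.0 mm)
```

All tract instances were generated (success rate 100%). The negative FA
mean difference (atlas minus pseudo-atlas) says the recipe-based
pseudo-atlas extraction reads higher FA — it stays on the bundle — while
the deliberately mismatched atlas labels spill into surrounding tissue
and CSF, depressing FA and inflating MD. The Evans' index ~0.30 reflects
the phantom's ventricle geometry.

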