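---
title: "Measuring 3D lamina cribrosa microarchitecture and its scan-rescan precision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D lamina cribrosa microarchitecture and its scan-rescan precision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The lamina cribrosa (LC) is the porous connective-tissue mesh in the optic
nerve head through which the retinal ganglion cell axons leave the eye. Its
*beams* (collagenous struts) and *pores* (axon-bundle channels) remodel in
glaucoma, so quantifying their 3D geometry in vivo — from swept-source OCT
volumes of roughly 3.5 × 3.5 × 3.64 mm at 400 × 400 × 896 voxels, i.e.
8.75 µm lateral and 4.0625 µm axial spacing — is of direct clinical
interest. Manual segmentation of thousands of pores is infeasible, and an
automated measurement is only useful if it is *reproducible*: a rescan of
the same eye a minute later, after refocusing, must yield nearly the same
numbers.

`lcmicro` implements the full measurement chain and the statistical
machinery to quantify that reproducibility, together with a synthetic
LC phantom generator so every stage can be validated against known ground
truth without patient data.

## The measurement chain

**Denoising.** A 3D median filter over a *physical ball* of radius
`denoise_radius` (default 10 µm). On the anisotropic grid the ball becomes
an ellipsoidal voxel neighbourhood; a per-axis box of "equivalent" radii
would span 3 × 3 × 5 voxels and measurably erodes pores that are only
~3 lateral voxels wide, which is why the ball is used.

**Analyzable-LC mask.** Only part of a scan shows usable LC: prelaminar
tissue covers it from above, the signal floor lies below, and blood vessels
cast shadows down entire columns. The mask combines three cues.

1. *Shadows*: columns whose mean intensity falls below half the median
   column signal are vessel shadows and are excluded.
2. *Texture*: LC tissue is marked where both the local signal (window
   mean) and the local contrast (window coefficient of variation, SD/mean)
   clear a threshold placed `mask_quality_quantile` (default 0.2) of the
   way between the robust low (5th percentile) and high (95th percentile)
   levels of each statistic. Contrast must be *relative* (CV, not SD):
   OCT speckle is multiplicative, so the bright but structureless
   prelaminar cap carries the largest residual noise SD in the scan while
   its CV stays low; conversely the noise floor has an enormous CV over a
   near-zero mean, which is why the contrast threshold is calibrated only
   among voxels that already carry signal. The statistics window is the
   lateral analysis window but axially short (~12 µm), keeping the cap-LC
   and LC-floor transitions sharp.
3. *Depth interval*: the interior of a thick beam is itself low-contrast,
   indistinguishable voxel-by-voxel from the cap. What distinguishes them
   is axial context — the cap lies *above* the first textured depth. Each
   column's analyzable interval therefore runs from its first to its last
   marked voxel, and everything inside the interval (including
   low-contrast beam cores) is analyzable; columns with fewer than 3
   marked voxels are dropped.

The result is morphologically opened and reduced to its largest connected
component, with shadow columns treated as *connective* during the
connectivity analysis (they hide LC, they do not interrupt it) and removed
afterwards — a shadow band punches holes in the region instead of
splitting it into competing islands. Fixed population quantiles were
considered for the thresholds and rejected: the fraction of junk voxels
varies between scans, so a fixed quantile either eats genuine LC or admits
junk; the robust-range formulation keeps the knob's meaning (0 =
permissive, 1 = paranoid) while adapting to the volume at hand.

**Beam/pore segmentation.** Within the mask, classification is by adaptive
local thresholding with a window of `local_window` (default 75 µm, about
1.5 beam widths). The first pass uses the plain window mean (zero offset).
Because beams occupy roughly twice the volume of pores, that mean sits
well above the midpoint of the two phase intensities, and under speckle it
systematically misassigns boundary voxels to the darker phase. The
threshold is therefore refined by *local isodata* (Ridler–Calvard)
iterations: at each voxel the threshold becomes the midpoint of the window
means of the two current classes, and the labelling is recomputed until
stable (at most 10 passes; 2–4 in practice). On noise-free two-level
phantoms the first pass is already exact and the refinement changes
nothing; at speckle contrast 0.3 it raises pore Dice from ~0.76 to ~0.90.
Finally, connected components of either phase smaller than `min_component`
(default 1000 µm³, ~3 voxels) are merged into their surroundings,
iterated to a fixed point so the cleanup is idempotent. Every threshold is
relative to local averages, so the segmentation is exactly invariant to
global intensity rescaling — refocusing between scans changes brightness,
not labels.

**Morphometry.** Pore diameter and beam thickness are *local thickness*
values: at each voxel, the diameter of the largest sphere that contains
that voxel and fits entirely inside the phase. Spheres are physical
(µm) spheres — the distance transform uses the per-axis spacing, because at
8.75 vs 4.06 µm voxels a voxel-count sphere would be wrong by more than a
factor of two. The implementation computes an exact anisotropic Euclidean
distance transform (separable lower-envelope algorithm), reduces candidate
sphere centres to the distance ridge (a centre is dropped only when a
neighbour's sphere provably contains its own), and paints the surviving
spheres; the result equals the brute-force definition voxel for voxel, and
the test suite verifies that equality against an independent
pair-enumeration oracle. The analyzable-mask boundary is treated as
structure boundary, so spheres cannot extend into unanalyzed tissue; this
biases thickness low at the mask edge, consistent with how the analyzed
region behaves at its rim in the clinical setting. Mean and SD are
voxel-weighted over the phase (every voxel's sphere diameter counts
equally), and the beam-to-pore ratio is defined as the ratio of the two
means, exactly.

Pore area and aspect ratio are measured per C-mode slice: 8-connected pore
components fully inside the mask (touching neither OUTSIDE nor the image
edge), at least 4 pixels; area is pixel count × dx × dy and the axes come
from the moment-equivalent ellipse of the pixel set (second central moments
in µm, plus the uniform-rectangle moment of a single pixel so that thin
components keep a positive minor axis). Pore *areas* are pooled over all
components of all slices by default; averaging per slice first is available
(`per_slice_pore_area`), since either reading of "average area of every
pore" is defensible. Pore counts per depth half (split at the axial
midpoint of the occupied slice range, ties to the top half) are reported
for inspection but deliberately not fed to the repeatability statistics:
counts reflect how much LC was visible in a particular scan, not an
intrinsic tissue property.

## The phantom

No generative model of LC microstructure is established in the literature,
so the package uses the standard porous-media surrogate: a Gaussian random
field, smoothed anisotropically and thresholded. The pore phase is the
sub-threshold set. Two knobs — the smoothing scale (µm) and the pore-phase
quantile — are *calibrated* so that running the package's own sphere-fitting
morphometry on the truth labels reproduces the requested pore diameter and
beam thickness within 5%; the calibration is deterministic (fixed internal
seed, fixed 96 × 96 × 64 calibration grid at study spacing), cached per
target set, and the resulting parameters are shared by all phantoms with
the same targets. En-face anisotropy of the smoothing kernel produces
elongated pores (target aspect ratio ~2, matching adult LC morphometry);
the elongation is approximate, not calibrated, because the thickness
targets constrain the kernel first.

Default targets are pore diameter 24 µm, beam thickness 49 µm, LC slab
depth 280 µm — the centre of published adult LC morphometry — on a
128 × 128 × 96 grid at study spacing (full 400 × 400 × 896 volumes are
supported; the smaller default keeps a full phantom-and-measurement cycle
around ten seconds of CPU). Above the slab sits a smooth bright prelaminar
cap (so the mask has something to exclude), below it a low noise floor.
Speckle is multiplicative unit-mean gamma noise with coefficient of
variation `speckle_contrast` (default 0.3 — strong but realistic for
OCT before averaging); vessel shadows are straight bands through the
en-face plane, 50–120 µm wide, attenuating their columns to 25%, covering
`shadow_fraction` (default 0.1) of the area.

A *repeat scan* differs from the original by a small rotation about the
slow scanning axis, a sub-voxel translation, a multiplicative contrast
change (refocus), and a fresh speckle realisation. Crucially, the rescan
transforms the phantom's *continuous* tissue model — the smooth field is
resampled with tricubic (Catmull-Rom) interpolation, the region map by
nearest neighbour, out-of-volume samples extend the edge values (tissue
continues beyond the scanned cube), and the beam/pore labels are re-derived
by thresholding the transformed field at the same slab quantile — rather
than resampling the rasterised labels or intensities. Two real scans of
one eye are exchangeable samples of the same tissue; resampling rasters
violates that (linear interpolation blurs, nearest-neighbour jags, and
interpolation slightly compresses the field's marginal distribution, each
only in the rescan), and those asymmetries masquerade as measurement
imprecision. With the continuous-model rescan, an identical pipeline run
on both scans differs only through speckle, the perturbation geometry and
residual interpolation error.

What the phantom does *not* emulate: wave-optical speckle statistics and
depth-dependent signal decay of a real SS-OCT instrument, eye-motion
artifacts (inputs are assumed motion-corrected), curved or focally
defective laminar plates, and vessel geometry beyond straight bands.
Passing tests on phantoms therefore demonstrate the correctness and
stability of the *measurement chain* under controlled perturbations, not
the clinical accuracy of any particular scanner.

## Repeatability statistics

Each eye is scanned twice with the instrument refocused in between, and
some subjects contribute both eyes, so measurements are nested: replicate
within eye within subject. Because the identical algorithm processes both
scans, the method bias is fixed at 1 and the measurement-error model
reduces to the nested random-effects decomposition

$$ y_{ser} = \mu + a_s + b_{e(s)} + \varepsilon_{ser}, $$

with subject effects $a_s$, eye-within-subject effects $b_{e(s)}$ and
replicate error $\varepsilon$. The *imprecision SD* is the residual SD
$\hat\sigma_\varepsilon$, estimated by REML (`lme4`); the *relative
imprecision* is $100\,\hat\sigma_\varepsilon/\bar y$ with the grand mean
over all scans of all eyes as denominator. Modelling the eye level matters:
anatomical between-eye differences would otherwise inflate the error term.
In the balanced two-replicate design the REML residual equals the
within-eye mean square, $\sqrt{\sum_i d_i^2 / 2n}$ over the paired scan
differences $d_i$ (the expected difference is zero under unit bias), and
the test suite verifies that equivalence to 1e-8 — reached by running the
optimizer (bobyqa) to a tight tolerance, which costs nothing at these data
sizes. When no subject contributes both eyes the eye-within-subject level
is unidentifiable (it coincides with the subject level); the model is then
fitted without it and the eye variance reported as `NA` — keeping the
redundant term would only add a flat likelihood ridge for the optimizer to
wander on. If REML fails outright the ANOVA method-of-moments components
are used, truncated at zero, and flagged. When the two replicates are
exact duplicates the estimate is returned as exactly zero without invoking
the optimizer.

Group comparisons (e.g. diagnostic categories) use the residual-variance
ratio with a seeded bootstrap confidence interval, resampling eyes with
their replicate pairs within each group. Inside the bootstrap the residual
variance is recomputed by its balanced-case closed form rather than a
thousand REML refits — the same estimand, at a thousandth of the cost. No
particular significance procedure is canonical for this comparison; the
bootstrap CI is this package's choice and is labelled as such.

## The in-silico reproducibility experiment

`run_repro_experiment()` is the computational analogue of a clinical
repeatability study: *n* phantom eyes (default 12, of which 4 subjects
contribute both eyes), each "scanned" twice with the default between-scan
perturbation — 1° rotation, half-voxel shift, 10% contrast change, fresh
speckle — the full pipeline measuring every scan, and the nested model
fitted per parameter. The master seed fans out per-eye and per-replicate
sub-seeds through a counter scheme, so enlarging the cohort never perturbs
the data of earlier eyes, and the whole experiment is bit-reproducible.
An identity perturbation means nothing changed between scans — including
the speckle realisation — so replicate measurements are bit-identical and
every relative imprecision is exactly 0%, which pins the statistical
machinery itself.

## Numerical choices and edge cases

* Distance comparisons in the thickness transform use strict inequality on
  squared distances ("a sphere contains the voxels strictly inside its
  radius"); with integer-valued squared distances on isotropic test grids
  the oracle comparison is exact, with no tolerance.
* Voxels beyond the array and OUTSIDE-labelled voxels count as background:
  inscribed spheres must fit inside the analyzed region.
* The ridge reduction keeps a centre unless a neighbour's sphere contains
  it with a 1e-9 µm margin — over-keeping is harmless, over-dropping would
  not be.
* Median windows clipped at volume borders use the lower median of the
  clipped sample, so the filter always returns an existing intensity.
* The speck-removal fixed point exists because each pass only reassigns
  components below a fixed size; in practice it terminates in one or two
  passes.
* Degenerate inputs fail loudly: an all-zero volume has "no analyzable
  LC"; a segmentation missing either phase cannot be measured; eyes without
  exactly two replicates are named in the error.
* `mask_quality_quantile` trades coverage against conservatism; at the
  default 0.2 the mask covers >99% of the true slab on noise-free phantoms
  while excluding the cap, floor and shadows. Raising it toward 0.5 gives
  visibly conservative masks (the behaviour described for the clinical
  tool).

## Problem sizes used in validation

The shipped tests and the acceptance script use the 128 × 128 × 96 phantom
grid (12-eye cohorts for the reproducibility experiment, 5 seeds for
parameter recovery, 500 Monte-Carlo repetitions for estimator recovery,
20 random ≤12³ volumes for the brute-force oracle). These sizes make a
full validation cycle a few CPU-minutes; all components accept full-size
400 × 400 × 896 volumes unchanged.

## Known limitations

* Phantom realism is structural, not radiometric: intensity statistics of
  a real SS-OCT prototype are not reproduced, only the contrast ordering
  (beams bright, pores dark, shadows darker).
* Voxel-wise cross-scan Dice under rotation is geometry-limited: at 2° the
  nearest-neighbour-rotated truth itself agrees with the original on only
  ~83% of slab voxels, so cross-scan Dice of the narrow pore phase cannot
  approach 1 however good the segmentation; parameter-level statistics are
  the meaningful cross-scan comparison and are what the reproducibility
  experiment scores.
* The local-thickness mean is voxel-weighted, which up-weights large
  structures relative to a per-component mean; this matches the "average
  all diameters" convention but should be kept in mind when comparing
  against component-weighted reports.
* Pore counts are reported but are not comparable across scans with
  different analyzable regions; they are excluded from imprecision
  statistics by design.
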