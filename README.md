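# lcmicro

Automated analysis of the three-dimensional microarchitecture of the human
lamina cribrosa (LC) in OCT volumes, and of how reproducible that analysis
is between repeated scans of the same eye.

The LC is the porous collagen mesh in the optic nerve head through which
retinal ganglion cell axons exit the eye; its **beams** (struts) and
**pores** (axon channels) remodel in glaucoma. `lcmicro` is aimed at
researchers building or validating in-vivo LC imaging pipelines: it provides
the measurement chain (denoising → conservative analyzable-LC masking →
adaptive local-threshold beam/pore segmentation → sphere-fitting
morphometry), the repeatability statistics, and a synthetic LC phantom
generator with known ground truth so that every stage can be tested without
patient data.

## The measurements

For a segmented volume the package reports the seven standard LC
microarchitecture parameters:

| parameter | definition |
|---|---|
| pore diameter (mean, SD), µm | local thickness of the pore phase |
| beam thickness (mean, SD), µm | local thickness of the beam phase |
| beam-to-pore ratio | beam mean / pore mean |
| pore area, µm² | mean area of en-face (C-mode) pore cross-sections |
| pore aspect ratio | mean major/minor axis of the moment-equivalent ellipse |

**Local thickness** at a point *p* of a phase is the diameter of the largest
sphere *S* ⊆ phase with *p* ∈ *S* (maximal inscribed sphere). Spheres are
physical µm spheres on the anisotropic voxel grid (8.75 µm lateral ×
4.0625 µm axial at the default scan geometry). The implementation — exact
anisotropic Euclidean distance transform, distance-ridge reduction, sphere
painting — is verified voxel-for-voxel against a brute-force enumeration
oracle in the test suite.

**Imprecision** of a parameter is the residual SD σ̂ of the nested
measurement-error model

    y_ser = µ + subject_s + eye_e(s) + ε_ser,   imprecision = SD(ε)

fitted by REML to two replicate scans per eye, with the method bias fixed at
1 (the same algorithm measures both scans) and the eye-within-subject level
keeping anatomical between-eye variation out of the error term. Relative
imprecision is 100 · σ̂ / ȳ.

## Worked example

```r
library(lcmicro)

# a synthetic LC: pore diameter 24 um, beam thickness 49 um, 280 um slab,
# speckle contrast 0.3, 10% vessel shadows, on a 128 x 128 x 96 grid
ph <- generate_phantom(phantom_spec(seed = 7))
ph$truth_params
#> LC microarchitecture parameters
#>   pore diameter     24.64 (SD 8.13) um
#>   beam thickness    48.22 (SD 13.81) um
#>   beam/pore ratio   1.957
#>   pore area         1849.8 um^2, aspect ratio 2.52
#>   slices with pores 69; pores top/bottom half 4281/4022

# measure the noisy scan the way a real scan would be measured
params <- run_single_scan(ph$volume)
params$pore_diameter_mean
#> [1] 25.6598
params$beam_thickness_mean
#> [1] 49.69785
```

The pipeline recovers the generator's targets (24 / 49 µm) to within a few
percent through speckle, shadows and masking. An in-silico scan-rescan
study — 12 phantom eyes, each "scanned" twice with a 1° rotation,
half-voxel shift, 10% contrast change and fresh speckle — then quantifies
reproducibility exactly as a clinical repeatability study would:

```r
res <- run_repro_experiment(pipeline_config(seed = 1))
res$report[, c("parameter", "mean_value", "imprecision_sd",
               "relative_imprecision_pct")]
```

Each row is one parameter's grand mean, imprecision SD and relative
imprecision over the simulated cohort; under the default perturbation all
parameters stay in the single-digit percent range, and under an identity
perturbation they are exactly 0%.

Repeated-measurement tables from real studies (long CSV: `subject_id`,
`eye_id`, `group`, `replicate`, `parameter`, `value`) can be analysed
directly with `fit_measurement_error_model()`, `imprecision_by_group()` and
`compare_group_imprecision()`.

A thin command-line front end is installed with the package
(`inst/scripts/lcmicro`): `simulate`, `repeat`, `segment`, `measure`,
`repro` subcommands over TIFF-stack volumes with JSON sidecars.

## Testing

```r
# full suite (a few CPU-minutes; includes the end-to-end cohort experiment)
testthat::test_dir("tests/testthat", package = "lcmicro",
                   load_package = "installed")
```

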