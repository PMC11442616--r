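# alpsdti

Glymphatic-system assessment with the DTI-ALPS index in brain-tumor
cohorts, as a tested, reusable R pipeline.

The glymphatic system is the brain's proposed waste-clearance pathway: CSF
and interstitial fluid flow along perivascular spaces, carrying metabolites
out of the parenchyma. DTI-ALPS (diffusion tensor imaging **a**long the
**p**erivascular **s**paces) probes this noninvasively. At the level of the
lateral-ventricle body, medullary veins — and their perivascular spaces —
run right–left (x), perpendicular both to projection fibers (feet–head, z)
and association fibers (anterior–posterior, y). From the per-voxel diffusion
tensor D, with 2×2-voxel ROIs on one slice in the projection and
association areas,

```
ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
```

An index near 1 means no preferential x-axis diffusivity; impaired
perivascular flow lowers it. In the packaged 24-patient unilateral-tumor
cohort the index is lower in the tumor-bearing hemisphere than
contralaterally, the study's central finding.

## What the package does

- **DWI I/O** — 4D NIfTI volumes with FSL-style `.bval`/`.bvec` gradient
  tables (`read_dwi()`, `read_gradient_table()`), scalar maps with JSON
  metadata sidecars. Directions live in a fixed patient frame
  (x = right–left, y = anterior–posterior, z = feet–head); ROIs use 0-based
  voxel starts and half-open extents.
- **Tensor fitting** — log-linear ordinary least squares per voxel
  (`fit_dti()`), FA / mean-diffusivity / S0 maps, and the trace-image ADC
  (`trace_adc_map()`: geometric mean of the b = 1000 volumes, then
  `ln(S_b0/S_trace)/b`).
- **ALPS extraction** — ROI-mean diffusivities of 2×2×1 ROIs
  (`roi_mean_diffusivities()`), the index itself (`compute_alps_index()`,
  `alps_from_fit()`), sub-voxel circular tumor-ADC ROIs (`tumor_roi_adc()`,
  default 5.3 mm²), and an advisory FA-gated ROI suggester
  (`suggest_roi()`).
- **Digital phantom** — a periventricular multi-compartment phantom with
  known tensors and a designed ALPS value (`default_phantom_spec()`,
  `build_phantom_tensors()`), mono-exponential signal simulation with
  seeded Rician noise (`simulate_signal()`), plus a synthetic cohort
  generator (`generate_cohort_table()`).
- **Cohort statistics** — Wilcoxon signed-rank and Mann–Whitney U with the
  conventions of the original analysis toolbox (exact enumeration at small
  n, tie-corrected normal approximation otherwise), OLS regression,
  report-style descriptives, and ±2-year sex/age control matching
  (`match_controls()`).
- **Study driver** — `run_study()` over the packaged per-subject tables
  (`alps_patients()`, `alps_controls()`), `emit_report()` for
  JSON/CSV/Markdown output, ggplot figures (`plot_alps_hemispheres()`,
  `plot_alps_regression()`).

A thin command-line front end lives at `inst/scripts/alps-study.R`
(subcommands `fit`, `alps`, `run`, `simulate`).

## Worked example

```r
library(alpsdti)

report <- run_study(alps_patients(), alps_controls())
report
#> DTI-ALPS study report
#>   24/30 patients included (14 male, 10 female; 17 primary, 7 metastasis), 12 controls
#>   ALPS ipsi 1.26 +/- 0.24 (median 1.22) vs contra 1.43 +/- 0.28 (median 1.36), signed-rank p = 6.69e-05
```

The tumor-side index (1.26 ± 0.24) is lower than the contralateral one
(1.43 ± 0.28); the paired signed-rank p ≈ 6.7e-5 says the within-patient
drop is highly unlikely under symmetry. Regressions find no linear relation
of the ipsilateral index with age (R² ≈ 0.001) or tumor ADC (R² ≈ 0.09).

End-to-end validation on the phantom:

```r
gt    <- default_gradient_table()          # 1 b=0 + 64 directions, b=1000
truth <- build_phantom_tensors(default_phantom_spec("contralateral"))
truth$designed_alps
#> [1] 1.4
vol  <- simulate_signal(truth, gt, noise_sigma = 1000/30, seed = 1)  # SNR 30
fit  <- fit_dti(vol, gt)
rois <- default_phantom_rois()
alps_from_fit(fit, rois$projection, rois$association)$index
#> [1] 1.466571
```

A single SNR-30 realization scatters around the designed 1.40 (the four
ROI diffusivities average only 4 voxels each); averaged over 10 seeds the
recovered index lands within 2% of the design, and on noiseless data the
full chain reproduces it to ~1e-14 with every tensor element recovered to
better than 1e-9 relative error — all asserted in the test suite.

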