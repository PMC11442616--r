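---
title: "Measuring glymphatic function with DTI-ALPS: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring glymphatic function with DTI-ALPS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsdti)
```

## The measurement model

Diffusion MRI encodes, per voxel, the signal attenuation
$S_i = S_0\,\exp(-b_i\, g_i^\top D\, g_i)$ for b-value $b_i$ and unit
direction $g_i$, where $D$ is the symmetric diffusion tensor (mm²/s). The
packaged acquisition model mirrors a clinical tumor-protocol DTI: one
$b = 0$ volume plus 64 directions at $b = 1000$ s/mm², 2 mm isotropic
voxels, with axes fixed as x = right–left, y = anterior–posterior,
z = feet–head. Gradient directions are interpreted in this image frame and
never reoriented by an affine; scanner exports differ in bvec sign/frame
conventions, and fixing one frame shared by simulation and fitting removes
that ambiguity from everything downstream (it is a package convention, not
a claim about any particular scanner).

At the level of the lateral-ventricle body the medullary veins and their
perivascular spaces run along x, perpendicular to the dominant axons of the
projection area (along z) and the association area (along y). The DTI-ALPS
index

$$\mathrm{ALPS} \;=\; \frac{\mathrm{mean}(D_{xx}^{proj},\, D_{xx}^{assoc})}
{\mathrm{mean}(D_{yy}^{proj},\, D_{zz}^{assoc})}$$

compares x-diffusivity in both areas against the diffusivities
perpendicular to both the fibers and the perivascular direction. Under pure
fiber anisotropy with no perivascular contribution the four quantities are
all "cross-fiber" diffusivities and the ratio is ~1; perivascular water
motion elevates the numerator specifically. The index is scale invariant
(multiplying all four diffusivities by a constant leaves it unchanged) and
inverting numerator and denominator maps it to its reciprocal — both are
enforced as tests.

Two caveats shape interpretation and are inherited by this implementation:
the diagonal elements $D_{xx}, D_{yy}, D_{zz}$ are *not* rotation
invariant (that is the method's premise, and the package tests that FA is
invariant under tensor rotation while $D_{xx}$ is not), so the index is
meaningful only in the stated patient frame; and the index reflects any
process that changes diagonal diffusivities, not perivascular flow alone.

## Tensor estimation

`fit_dti()` solves, per voxel, the linear system
$\ln S_i = \ln S_0 - b_i\, g_i^\top D\, g_i$ by ordinary least squares in
the seven unknowns $(\ln S_0, D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz},
D_{yz})$. Choices that matter:

* **Unweighted OLS, no nonlinear refinement.** Deterministic, exact on
  noiseless data (residuals below 1e-10 in log space are asserted in the
  tests), and the estimator differences that weighted/nonlinear schemes
  introduce are far below the ROI-averaging noise at the SNRs of interest.
* **No positivity constraint.** The ALPS index is defined on raw diagonal
  elements; eigenvalue clipping would bias the statistic it feeds.
* **Signal floor** of $10^{-6}\cdot\max(S)$ before the log, so magnitude
  noise at high b never produces $-\infty$; the floor only engages on
  voxels that are effectively background.
* **Rank check.** Fitting requires at least one $b=0$ measurement and six
  $b>0$ directions whose quadratic forms have rank 6; collinear or coplanar
  schemes are rejected up front rather than producing garbage tensors.

The trace ADC is computed as the study defines it: a trace image as the
per-voxel *geometric* mean of the $b = 1000$ volumes, then
$\mathrm{ADC} = \ln(S_{b0}/S_{trace})/b$. With the geometric mean this
equals the tensor-model mean diffusivity exactly in the noiseless limit,
which the tests exploit as an internal consistency check against
$(D_{xx}+D_{yy}+D_{zz})/3$.

## ROIs

Projection/association ROIs are fixed at 2×2 voxels on a single slice
(4×4 mm² in-plane at 2 mm voxels), the footprint the method prescribes;
resizing requires an explicit override. ROIs are inputs — voxel
coordinates, 0-based with half-open extents, read from a JSON sidecar —
because expert consensus placement has no algorithmic definition. The
advisory `suggest_roi()` scans 2×2 windows on a slice for maximal
principal-eigenvector alignment with z (projection) and y (association)
under an FA ≥ 0.2 gate; it is never silently substituted when explicit
coordinates are supplied.

The tumor ADC ROI is a circle of 5.3 mm², which is *smaller than a single
2×2 mm voxel footprint*, so the rasterization rule must be explicit to be
testable: voxels belong to the ROI when their center falls inside the
circle, and the voxel containing the ROI center is always included. At the
default area the ROI therefore reduces to the center voxel unless the
center sits near a voxel-corner; larger areas grow the disc as expected.

## The digital phantom

The phantom emulates the periventricular geometry on a 20×20×5 grid of
2 mm voxels: a central CSF "ventricle" (isotropic 3.0e-3 mm²/s), a
projection-fiber box (principal diffusivity 1.7e-3 along z), an
association-fiber box (1.7e-3 along y), an isotropic "tumor" (1.6e-3,
matching the magnitude of the cohort's tumor ADC values), and isotropic
background (0.8e-3). Perivascular water is represented as elevated
$D_{xx}$ in the fiber compartments — the single-tensor reading of the ALPS
mechanism itself; a genuinely multi-compartment voxel model would change
the biophysics being simulated but not what the pipeline measures from the
resulting tensors. The "contralateral" variant designs an index of 1.40,
the "ipsilateral" variant 1.25 (echoing the cohort's group magnitudes),
and an isotropic variant designs exactly 1.

Noise is Rician — the magnitude-MRI model — built from two seeded Gaussian
channels: $\tilde S = |S + n_1 + i\,n_2|$. Determinism under a seed is a
contract, tested. The 64-direction scheme ships as a text fixture produced
once by a deterministic electrostatic-repulsion layout (antipodally
symmetric energy, Fibonacci-hemisphere start); its directions are stored at
six decimals, so unit norms hold to ~1e-6 and closed-form "exact" checks on
this scheme carry that tolerance.

What passing phantom tests shows — and what it does not: the chain
simulate → fit → ROI-average → index is self-consistent, unbiased at the
designed tensors, and stable at SNR 30 (designed index recovered within 2%
averaged over 10 seeds; an isotropic phantom yields 1 ± 0.05). The phantom
deliberately omits EPI distortion, motion, eddy currents and
partial-volume CSF contamination, so these results say nothing about those
real-data failure modes; they validate the arithmetic, not the acquisition.

## Statistical conventions

The cohort analysis reproduces the conventions of the toolbox the study
used, and two of them are load-bearing for matching its printed values:

* **Wilcoxon signed-rank** (hemisphere comparison): zero differences
  discarded (a Pratt-style variant is available behind `zero_method`),
  midranks on $|d|$, statistic $W = \min(W^+, W^-)$. Exact p by full
  enumeration of the $2^n$ sign assignments for $n \le 15$; above that, a
  normal approximation with tie-corrected variance and **no continuity
  correction**. On the packaged pairs ($n_{\mathrm{eff}} = 23$ after one
  tied pair) this yields p = 6.69e-5; adding a continuity correction gives
  7.13e-5 and exact enumeration 3.3e-6, so the convention is identifiable
  from the printed value and is pinned by an acceptance test.
* **Mann–Whitney U** (subgroups): midranks, exact enumeration when the
  pooled size is ≤ 12 without ties, otherwise tie-corrected normal
  approximation **with** a 0.5 continuity correction. This reproduces the
  printed subgroup p-values (0.51 age, 0.46 sex, 0.53 tumor type, 0.065
  ROI-in-edema).
* **Descriptives**: sample sd; even-n medians are convention-free and used
  as acceptance values. Quartiles use the midpoint-of-halves convention
  with the median excluded — the report's own quantile convention is
  unstated, so printed Q1/Q3 are not treated as reproducible targets.
* **Rounding** is half-away-from-zero at 2 decimals, applied only at the
  reporting layer (`round_half_away()`); all stored values keep full
  precision.
* **Regression** is plain OLS via `lm()`, slope p from the t distribution
  with $n-2$ df. The regression pairing that reproduces the printed
  R² = 0.09 is ipsilateral index vs tumor ADC; contralateral-index-vs-age
  recomputes to R² = 0.0295 (p = 0.4223) from the packaged rows — its
  printed p matches but a printed R² of 0.003 is internally inconsistent
  with that p at n = 24, so the package reports the recomputed value.

**Control matching** is greedy nearest-age within ±2 years and equal sex,
controls reusable across patients (the packaged mapping reuses controls up
to four times), ties broken toward the lowest control id. Two things keep
the matched-control comparison out of the acceptance surface. First, the
packaged control table cannot satisfy the strict ±2-year rule for one
patient (male, 38; the nearest male control is 41) even though the cohort's
own mapping pairs exactly those two — so runs on the packaged tables use a
3-year tolerance, and the strict default demonstrates the error contract.
Second, the hemisphere-selection convention (which control hemisphere
stands in for "ipsilateral") is not derivable from the published group
means, so `run_matched_comparison()` exposes it as an explicit
`hemisphere_rule` parameter (`tumor_side`, `fixed_left`, `fixed_right`)
rather than baking in a guess.

The age dichotomy is strictly < 55 vs > 55; no packaged subject is exactly
55, so the boundary never engages, but the rule is documented and subjects
at the cut would belong to neither group.

## Synthetic cohorts

`generate_cohort_table()` draws paired hemisphere indices from a bivariate
normal with the study's group parameters (ipsi 1.26 ± 0.24, contra
1.43 ± 0.28, n = 24; controls 1.27 ± 0.22, n = 12) and a within-subject
correlation of 0.8 — paired hemispheres in one brain are strongly
correlated, and a near-zero correlation would grossly understate the
paired-test power the study actually had. Ages are uniform over 24–73,
sexes Bernoulli at 14/24 male. Under these defaults the paired signed-rank
test rejects at better than 90% power across 200 seeded replicates, and
the empirical type-I level of both tests sits in [0.03, 0.07] over 2,000
null simulations — both asserted in the test suite. The generator emulates
the *statistical* structure of the cohort only; it draws normal indices
and independent tumor attributes, so it cannot stand in for real
per-subject covariance beyond the configured pairing.

## Problem sizes and numerical choices

The test suite runs the full phantom chain on the 20×20×5 grid (2,000
voxels × 65 measurements — a desk-scale problem that keeps the whole suite
under ~15 s), 100-tensor recovery checks, 2,000-replicate null
calibrations and 600 power-simulation fits. Tensor recovery on noiseless
data is asserted to 1e-9 relative error per element (scaled by each
voxel's largest element magnitude, since exact-zero off-diagonals make
plain relative error meaningless); the full noiseless pipeline reproduces
the designed index to 1e-6. Degenerate inputs have defined behavior
throughout: all-tied pairs raise "no effective pairs", empty masks and
rank-deficient schemes fail fast, FA of degenerate (non-positive-trace)
voxels is 0, and one-member subgroups report descriptives without an sd.

## Known limitations

* ROI placement on real data remains expert work; `suggest_roi()` is a
  geometric heuristic with an FA gate, not a substitute for consensus
  reading, and it has only been validated on phantom geometry.
* The pipeline deliberately omits motion/eddy/EPI-distortion correction;
  volumes are assumed preprocessed.
* Single-shell, single-tensor modeling only; no free-water elimination, so
  CSF partial voluming biases periventricular tensors on real data.
* The matched-control analysis depends on an unstated hemisphere
  convention (exposed as a parameter, see above), and the packaged control
  table supports several equally defensible pairings.
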