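---
title: "How octscan quantifies OCT scanning-parameter trade-offs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How octscan quantifies OCT scanning-parameter trade-offs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`octscan` answers one question about macular OCT monitoring of exudative
disease: how much detection sensitivity and volumetric accuracy for IRF,
SRF and PED is lost when the scan covers less area (smaller field of view,
FOV) or samples it more sparsely (larger interscan distance, ISD)? This
vignette is the package's own account of the models, conventions and design
decisions behind each stage. Everything here is asserted by the test suite
or computed by `scripts/acceptance.R`; no empirical claim below goes beyond
what that code produces.

## Coordinate and geometry contract

A `SegVolume` is an integer label array indexed `[bscan, depth, ascan]`:
axis 0 is the slow axis (y), axis 2 the fast axis (x), axis 1 depth. The
en-face plane is `(y, x)`. `ScanGeometry` makes the physical interpretation
explicit and is always read from a JSON sidecar, never from container
headers, because exporters disagree about header conventions and a silent
unit error would poison every downstream number.

B-scan `i` (0-based) sits at `i * isd`, so the positions span the closed
interval `[0, fovY]` and `(nBscans - 1) * isd == fovY` is a class
invariant: 49 B-scans at 125 µm cover exactly 6 mm. A-scan `i` sits at
`i * pitch` with `pitch = fovX / nAscans`. The default grid uses 480
A-scans rather than a power of two so that the pitch is exactly 12.5 µm and
a 250 µm crop step is exactly 20 pixels — all crop-boundary comparisons in
the FOV analysis are then exact in binary floating point and need no
tolerance.

One label per voxel is a deliberate simplification (clinical annotation
tools keep one mask per biomarker, in which fluids could in principle
overlap). Every per-biomarker operation takes a biomarker argument, so a
future multi-mask backend would change only the I/O module. The pooled
biomarker `IRF_SRF` (voxels labeled IRF *or* SRF) is computed at voxel
level and then flows through every stage like a fourth biomarker, because
treatment guidelines often treat any fluid presence equivalently.
`retina` denotes everything from ILM to Bruch's membrane and therefore
counts labels {retina, IRF, SRF} but not PED, which lies below Bruch's
membrane.

## Orientation normalization

Left eyes are mirrored along x so that +x always points nasal and left and
right eyes superimpose anatomically in population maps. `mirrorIfLeft()`
flags the volume as normalized and is idempotent — applying it twice cannot
flip a volume back, which matters in pipelines that re-enter the
preprocessing stage. The pure reflection `mirrorX()` (index `i -> n-1-i`,
an involution) is exposed separately for tests and tooling.

## Heatmaps and the Gaussian fit

Per eye and biomarker, voxels are summed along depth and the resulting
column counts binarized at a threshold of one voxel: presence only, no
minimum-size filter (`minColumnVoxels` exists as a hook, default 1). The
population heatmap is the elementwise mean over eyes — eyes, not patients,
are the aggregation unit, and biomarker-negative eyes stay in the
denominator so the map reads as "fraction of the cohort positive here".

The heatmap is fitted with the isotropic model
`A * exp(-((x - mu_x)^2 + (y - mu_y)^2) / (2 sigma^2))` by
Levenberg–Marquardt nonlinear least squares (`minpack.lm::nlsLM`, the
standard R counterpart of a `curve_fit`-style optimizer). Numerical
choices:

* **Coordinates.** The fit runs in physical micrometres, not pixel
  indices. The two axes have very different pitches (12.5 vs 125 µm by
  default); fitting in index space would silently stretch sigma.
* **Initialization** is parameter-free: `A0 = max(fraction)`, center at
  the intensity-weighted centroid, `sigma0` the weighted RMS radius
  divided by `sqrt(2)` (each axis contributes `sigma^2` to the radial
  second moment). `heatmapMoments()` exposes this closed-form estimate.
* **Bounds.** `A in [0, 1.5]`, `sigma in (0, max FOV]`, centers within
  the FOV extended by `sigma0`. These keep the optimizer off the flat
  plateaus that an unbounded Gaussian fit has at huge sigma.
* **Tolerances.** `ftol = ptol = 1e-15`, max 200 iterations; a heatmap
  that is exactly realizable by the model is recovered to better than
  1e-6 relative error in every parameter (asserted in the tests).
* **R²** is the ordinary coefficient of determination over all grid
  points, `1 - SS_res/SS_tot` with `SS_tot` about the heatmap mean. Pixels
  are weighted equally; an `areaWeighted` flag exists but is a no-op on
  the regular acquisition grid where all pixels share one area.
* **Degenerate inputs.** An identically zero heatmap is an error (there
  is nothing to fit). A constant nonzero heatmap has `SS_tot = 0`; R² is
  then reported as `NaN` with `converged = FALSE` rather than inventing a
  number. Optimizer failure returns the initialization with
  `converged = FALSE` instead of throwing.

## FOV crop sensitivity

The sensitivity map is indexed by crop *size*, not position: every crop is
centered on the FOV center, which stands in for the fovea since macular
scans are fovea-centered and the package does not localize the fovea
computationally. For each size pair `(wx, wy)` on a 250 µm grid the map
records the fraction of reference-positive eyes (positive anywhere in the
full volume) that remain positive inside the closed rectangle
`[cx - wx/2, cx + wx/2] x [cy - wy/2, cy + wy/2]`. Conventions:

* Closed intervals with boundary ties included — deterministic and
  symmetric; pixel positions and half-widths are exact binary fractions on
  the default grid, so no epsilon is involved.
* The denominator contains only reference-positive eyes (ordinary
  sensitivity); all-negative eyes cannot affect the map, which the tests
  assert by injection.
* Centered size-indexed crops were chosen over a sliding fixed-size
  window; with fovea-centered disease the centered reading is the
  clinically meaningful one (it models buying a smaller scan protocol),
  and the sliding variant is noted as an extension, not implemented.

Internally each eye is reduced to per-pixel distances from the center,
from which detection for all 576 size pairs follows; a brute-force
per-crop pixel re-scan oracle in the test suite confirms exact equality on
50-eye cohorts.

## ISD decimation, volumes and MAPE

Increasing ISD is simulated by repeatedly dropping every second B-scan:
factor `f = 2^k` keeps indices `{0, f, 2f, ..., n-1}`. Both border scans
are always retained — the only phase consistent with the border-corrected
volume rule below, which needs scans at the volume edges. `f` must divide
`nBscans - 1`, so the default 49-scan grid supports 125/250/500/1000 µm.

Volume estimation is piecewise-constant: each B-scan's biomarker
cross-section (voxel count × pitch × depth scale, in µm²) is multiplied by
its ISD, with the first and last scan half-weighted. The weights then sum
to exactly `fovY` at every factor (an exact floating-point identity on the
default geometry, asserted as such), so the analyzed volume is constant
regardless of ISD and any biomarker with a constant cross-section gets a
factor-independent estimate — both are acceptance properties. Volumes are
reported in true µm³ (the in-plane voxel area is included); all
downstream comparisons are relative, so the constant factor cancels, but
physical units make single numbers interpretable.

Quantification error is summarized as MAPE in percent over eyes, pairing
each eye's reduced-ISD estimate with its full-ISD reference. Pairs with a
zero reference are excluded from both the sum and `n` — the percentage
error is undefined there — and the exclusion count is reported. A cohort
with no positive reference yields `"n/a"` in tables rather than an error,
mirroring how clinical tables mark unavailable cells.

Detection sensitivity per factor is per *eye* (any biomarker voxel left in
the decimated volume), not per lesion. Per-B-scan counts are precomputed
once per eye and every factor's presence and volume derived from the
retained subset; this is algebraically identical to decimating and
recounting, and the tests verify exact equality against an explicit
slice-by-slice oracle.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage is testable and the full analysis
reproducible without clinical data. It emulates, per eye:

* **Anatomy.** A retina slab between a smooth, gently tilted Bruch's
  membrane (at 65% depth, tilt up to ±1% of the depth range) and an ILM
  derived from a 280–320 µm baseline thickness with a 100 µm Gaussian
  foveal depression (600 µm spread). Surfaces are low-order smooth
  functions; only label geometry matters downstream.
* **Prevalence.** Independent Bernoulli presence per biomarker: AMD preset
  IRF 0.25, SRF 0.55, PED 0.90; RVO preset IRF 1.0, SRF 0.42, PED 0.0.
* **Spatial structure.** Positive eyes get `1 + Poisson(1)` ellipsoidal
  lesions with en-face centers from an isotropic Gaussian about the FOV
  center, truncated to the FOV by rejection. `sigma_pop` is 800 µm (1200
  µm for RVO IRF, whose foveal concentration is weaker). The paper-grade
  clinical distributions publish no sigma; 800 µm puts most mass in the
  central 3 mm, which is what fovea-concentrated exudative AMD looks like
  in population maps.
* **Lesion sizes.** En-face semi-axes uniform in 100–600 µm, axial
  semi-axes 40–160 µm, with IRF inside the slab, SRF as a dome on Bruch's
  membrane, PED as a dome below it, written in priority order PED < SRF <
  IRF. No published size distribution exists; these are plausible for
  exudative macular disease, chosen once, and fully config-exposed. The
  lower radius bound of 100 µm is intentionally below the 125 µm reference
  ISD ladder step, so decimation can genuinely miss lesions. Each lesion
  additionally writes one guaranteed voxel at its center column, making
  "biomarker drawn present" and "present in the reference scan" coincide —
  empirical prevalence is then exactly binomial, which the calibration
  tests rely on.
* **Reproducibility.** One master seed; each eye derives a private
  substream from `(seed, index)` via a Lehmer-style hash kept below 2³¹,
  so single eyes regenerate identically in isolation and cohort order is
  irrelevant.

It does **not** emulate OCT intensities, speckle, motion artifacts,
segmentation errors, between-biomarker spatial correlation, or non-fluid
pathology. Consequently, passing tests demonstrate the *pipeline's*
correctness and the qualitative orderings (sensitivity monotone in crop
size, degradation with ISD, retina volume ISD-proof), not clinical effect
sizes: synthetic MAPEs and sensitivities depend on the assumed lesion-size
distribution and will not numerically match any particular clinic's
cohort. The synthetic total-retina MAPE (~0.01–0.03%) is smaller than
clinically reported (~0.1–0.3%) because the phantom's surfaces are
smoother than real segmentations.

## Problem sizes and determinism

The test suite exercises, among others: 50-eye cohorts at the full
49 × 496 × 480 study geometry for oracle equivalence, a 200-eye cohort
for the monotonicity sweeps and ordering checks, and a 500-eye cohort for
prevalence recovery (exact binomial 99% CIs) and Gaussian parameter
recovery (fitted center within 0.1 `sigma_pop`, fitted sigma within 20% of
the moment estimator on the same heatmap). Equivalence tests that only
compare algebra run on a compact 25 × 64 × 96 grid. All tests and the
acceptance script are seeded; reruns are bit-identical, including the
summary JSON written by `runAll()`.

## Known limitations

* Single-label voxels cannot represent co-occurring fluids at one voxel.
* The fovea is assumed at the FOV center; no per-eye fovea localization.
* Volume estimation is piecewise-constant in the slow axis; no
  interpolation between B-scans.
* The Gaussian model is isotropic by construction; elongated or rotated
  occurrence patterns will show up as a depressed R², not as anisotropy
  parameters.
* Off-center crop placement (optimizing window position per eye) is out
  of scope.
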