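# octscan

Scanning-parameter sensitivity analysis for retinal OCT fluid biomarkers.

## The problem

Macular OCT is the standard monitoring tool in exudative AMD and retinal
vein occlusion (RVO), where retreatment decisions hinge on detecting three
biomarkers in the volume scan: intraretinal fluid (IRF), subretinal fluid
(SRF) and pigment epithelium detachment (PED). Devices differ widely in two
acquisition settings — the en-face field of view (FOV) and the interscan
distance (ISD, the spacing between B-scans) — and both trade acquisition
time against the risk of missing small or off-center fluid pockets.

`octscan` quantifies that trade-off from labeled segmentation volumes
(codes: 0 background, 1 retina from ILM to Bruch's membrane, 2 IRF, 3 SRF,
4 PED), for ophthalmic imaging researchers and device designers:

* **Population heatmaps.** Each eye is orientation-normalized (left eyes
  mirrored so +x is nasal), projected along depth, and binarized to a
  presence map; the cohort mean gives the fraction of eyes positive at each
  en-face location. The heatmap is fitted with an isotropic 2D Gaussian

  `f(x, y) = A exp(-((x - mu_x)^2 + (y - mu_y)^2) / (2 sigma^2))`

  by Levenberg–Marquardt least squares in physical micrometre coordinates,
  with `R^2 = 1 - SS_res / SS_tot` reported.
* **FOV sensitivity maps.** For every fovea-centered crop size on a 250 µm
  grid up to the full 6 × 6 mm, the fraction of reference-positive eyes
  still detected inside the crop (closed-rectangle convention).
* **ISD degradation.** Every second B-scan is dropped repeatedly (factors
  2, 4, 8; e.g. 125 → 250 → 500 → 1000 µm), keeping both border scans.
  Detection sensitivity per level, plus volume estimates where each
  B-scan's cross-sectional area is weighted by its ISD with the two border
  scans half-weighted — so the weights always sum to the full 6 mm slow
  axis — and the mean absolute percentage error (MAPE)

  `MAPE = 100/n * sum_t |Reference_t - Reduced_t| / Reference_t`

  with zero-reference pairs excluded from `n`.
* **Synthetic cohorts.** A generator emulating Spectralis-style geometry
  (6 × 6 mm, 49 B-scans, 125 µm ISD) with layered retinal anatomy,
  fovea-centered Gaussian lesion placement, and AMD (IRF 25% / SRF 55% /
  PED 90%) or RVO (IRF 100% / SRF 42% / PED 0%) presets, so the whole
  pipeline is testable without clinical data.

I/O is NIfTI or multipage TIFF plus a mandatory JSON geometry sidecar, and
plain-CSV cohort manifests.

## Worked example

```r
library(octscan)

cfg <- cohortConfig(20, amdPreset(), seed = 42)
dir <- file.path(tempdir(), "amd20")
sampleCohort(cfg, dir)                       # writes volumes + manifest
bundle <- runAll(runConfig(file.path(dir, "manifest.csv")))

vapply(bundle$summary$prevalence, function(p) p$percent, numeric(1))
#>     IRF     SRF IRF_SRF     PED
#>      30      60      65      80

exemplarySensitivities(bundle$fovMaps$IRF_SRF)
#>      fov sizeUm sensitivity
#> 1   full   6000   1.0000000
#> 2 3x3 mm   3000   1.0000000
#> 3 2x2 mm   2000   1.0000000
#> 4 1x1 mm   1000   0.9230769

print(bundle$mape, digits = 3)
#>   factor effectiveIsdUm  IRF   SRF IRF_SRF   PED  retina
#> 1      2            250 10.2  5.98     8.2  3.21 0.00449
#> 2      4            500 21.1 19.92    21.8 15.40 0.01067
#> 3      8           1000 61.1 50.21    50.5 52.26 0.02639
```

Read: in this 20-eye synthetic AMD cohort, pooled IRF∪SRF detection
survives cropping to 2 × 2 mm untouched and drops to 0.92 at 1 × 1 mm;
fluid volume quantification already errs by ~3–10% at 250 µm ISD and
becomes unusable (>50%) at 1000 µm, while total retinal volume is
essentially ISD-proof — the fovea-concentrated, small-lesion structure of
exudative disease in a nutshell. `renderFigures(bundle, "figs")` draws the
heatmaps (with ETDRS 1/3/6 mm overlay), sensitivity maps and relative
volume boxplots.

A thin CLI over the same functions lives at `inst/cli/octscan.R`
(`generate`, `heatmap`, `fov`, `isd`, `run-all` subcommands).

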