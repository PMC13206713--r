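# choromap

High-density topographic mapping of choroidal structure and vascularity
from OCT macular cubes, for researchers quantifying choroidal change in
retinal disease (e.g. intermediate age-related macular degeneration)
against matched controls.

## What it computes

From a macular cube of B-scans (default protocol: 61 scans, 8.6 mm scan
length, 1.8 mm depth, 3.9 µm axial resolution) with RPE and
choroidoscleral boundary segmentations supplied as inputs, choromap
derives, on a fovea-centred 60 × 60 grid of 120 µm cells
(7200 × 7200 µm, ~3600 grid-level values per metric):

- **CT** — choroidal thickness, the RPE-to-choroidoscleral distance (µm);
- **LA / SA** — luminal and stromal area of the binarized choroid (µm²);
- **CVI** — the choroidal vascularity index, `CVI = LA / (LA + SA)`.

The choroid band is split into dark vessel lumen and brighter stroma by
**multiscale median-cut quantization** (recursive median splits of the
widest intensity bucket; darkest half of buckets = lumen; several window
widths combined by majority vote). Retinal-vessel shadow columns are
detected and excluded before any counting.

Two groups of eyes are compared per cell through the **symmetric percent
change** of the group medians,

```
Δ(x, c) = 100 · (x − c) / ((x + c) / 2)   ∈ (−200, 200),
```

and the resulting difference maps are analysed with ETDRS sectors
(1/3/6-mm rings + near periphery, Kruskal–Wallis across rings, Holm-
corrected per-sector Wilcoxon), with 0.05-mm **eccentricity bins**
(per-bin medians fitted by linear and quadratic least squares, the model
chosen by R²), with paired Wilcoxon global tests, and with Spearman
correlations between metrics. Model features — the eccentricity where a
linear model changes sign (`−k/m`) or a quadratic's vertex (`−b/2a`) —
are reported at 0.1 mm.

A synthetic macular-cube generator (`generate_volume`,
`generate_cohort`) produces volumes with per-pixel tissue labels and
exact per-cell truth, plus grid-level cohorts with prescribed
eccentricity effect profiles, so every pipeline stage is verifiable
without patient data. See the methods vignette
(`vignettes/choromap-methods.Rmd`) for the model, conventions and
verification design.

## Worked example

```r
library(choromap)

# a synthetic macular cube under the default protocol, with speckle noise
scene <- scene_params(noise_sd = 20, seed = 7)
gv    <- generate_volume(scene)
gv$volume
#> <oct_volume> 61 B-scans of 462 x 512 px (OD)
#>   A-scan 16.80 um, B-scan 120.0 um, axial 3.90 um; quality 30.0-30.0 dB

quantify_volume(gv$volume)
#> <cell_metrics_grid> 60x60 cells (3445 valid); median CT 280.0 um, CVI 0.627
```

All 3600 grid cells are produced; 155 cells under detected vessel
shadows are invalid (`NA`, never zero). The recovered median CT equals
the scene's 280 µm and the median CVI sits close to the generator's
0.65 lumen fraction.

```r
# a 40-vs-40-eye cohort with a quadratic CVI effect profile embedded
coh <- generate_cohort(cohort_spec(
  n_per_group    = 40,
  effect_profile = list(cvi = c(3.75, -19.67, 16.44)),
  seed           = 7))
dm  <- difference_map(coh$iamd, coh$control, "cvi")
fit <- fit_eccentricity_model(dm)
fit
#> <eccentricity_fit>
#>   linear:    y = -8.0756 x + 9.9841   (R2 = 0.8812)
#>   quadratic: y = 3.8359 x^2 + -20.1698 x + 16.9446   (R2 = 0.9947)
#>   chosen: quadratic; p = 4.333555e-61; bins = 56

model_features(fit)$reported
#> $vertex_mm
#> [1] 2.6
#> $extremum_value
#> [1] -9.6
#> $roots_mm
#> [1] 1

global_compare(coh$iamd, coh$control, "cvi")
#> median diff -5.90% [IQR -7.76, -3.10], p = 1.14e-07
```

The fitted quadratic recovers the embedded coefficients within a few
percent despite 3% between-eye and 6% per-cell noise; its vertex
(maximal loss at 2.6 mm eccentricity) and positive-to-negative crossing
near 1 mm are the spatial signature embedded by the profile: a central
CVI increase turning into parafoveal loss that bottoms out before the
near periphery.

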