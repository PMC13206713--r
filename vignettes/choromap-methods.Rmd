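---
title: "Methods: high-density choroidal mapping and its verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-density choroidal mapping and its verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

The choroid is the vascular bed between the retinal pigment epithelium
(RPE) and the sclera. On an OCT B-scan its large vessel lumina appear
hypo-reflective (dark) against the brighter stromal matrix, which makes
three quantities measurable per A-scan column: choroidal thickness (CT,
the RPE-to-choroidoscleral-junction distance), luminal area (LA) and
stromal area (SA). The choroidal vascularity index CVI = LA / (LA + SA)
summarises angioarchitecture as the luminal fraction of the total
choroidal cross-section, which also makes it robust to ocular
magnification.

choromap maps these metrics at high spatial density: a macular cube of
B-scans (61 scans, 8.6 mm scan length, 1.8 mm depth at 3.9 µm axial
resolution under the default protocol) is reduced to a fovea-centred
60 × 60 grid of 120 µm cells covering 7200 × 7200 µm, giving 3600
grid-level values per metric and eye. Group differences are expressed as
symmetric percent change per cell, and their spatial structure is read
through two templates: ETDRS sectors (1/3/6-mm rings plus a
near-periphery ring, split into quadrants) and eccentricity bins of
0.05 mm, on which linear and quadratic regression models of change
versus eccentricity are fitted.

Boundary segmentations (RPE and choroidoscleral curves) are taken as
inputs; the package does not segment the choroid itself.

## Binarization: largest-range median-cut quantization

Lumen/stroma separation uses median-cut quantization of the choroid band
intensities rather than a local threshold. The implementation follows
the classical median-cut scheme: starting from one bucket holding all
band pixels of a window, the bucket with the *widest intensity range* is
recursively split at its median value until `n_levels` buckets exist
(default 4; a bucket that has collapsed to a single grey level stops
splitting). The darkest half of the buckets is labelled lumen.

The largest-range rule matters. Splitting every bucket evenly would
produce equal-count buckets, and "darkest half" would then always label
~50% of pixels lumen regardless of the true luminal fraction. Splitting
the widest bucket instead concentrates the cut points around the broad,
sparsely populated valley between the dark lumen mode and the bright
stroma mode, so the darkest-half rule adapts to the true fraction: on a
noiseless bimodal band it reproduces the generating labels exactly, and
under heavy speckle-like noise (SD 20 grey levels on modes 60/180) the
test suite measures pixel agreement with truth above 95%.

The pass is multiscale: windows of 32 and 64 A-scan columns plus the
whole region are quantized independently and the per-pixel labels are
combined by majority vote (rules `any`/`all` are available). Local
windows adapt to lateral intensity gradients; the global window
stabilises columns where a window happens to be nearly unimodal. A
constant-intensity band carries no contrast and is labelled all-stroma
with a warning. Fraction recovery is sharpest when the band is clearly
bimodal; in the mid-range (true fractions near 0.5) the 4-level
quantization recovers the fraction more coarsely, though monotonically.

## Shadow exclusion

Retinal vessels attenuate everything beneath them, producing vertical
dark bands that corrupt choroidal intensities and must be excluded, not
measured. Each column is summarised by the 40% trimmed mean of its
pixels below the RPE: that statistic is dominated by the stable scleral
reflectance, so it responds to broadband attenuation of the whole column
but not to how much dark lumen (or bright stroma) the column happens to
cross. Summaries are smoothed with a width-3 running median — shadows
are several columns wide, single-column dips are vascular texture — and
a column is flagged when it falls below the B-scan median by more than
2 MADs *and* by more than 5% of the median. The contrast floor encodes
that a shadow is a multiplicative attenuation of sizeable depth; without
it, a purely relative cut on an approximately normal statistic flags
~2% of clean columns by construction. Flagged columns are dilated by one
column each side as a safety margin. Flagged columns keep no metric
values: downstream, cells are valid only when at least half of their
expected column samples survive.

## Grid aggregation

Each (A-scan, B-scan) sample maps to exactly one half-open 120 µm cell
by its fovea-centred coordinates. Per cell, CT is the *median* of valid
column thicknesses (medians are the reporting convention throughout the
package, chosen over means for robustness to segmentation outliers);
LA and SA are pooled pixel counts scaled by the pixel area, and CVI is
computed from the pooled counts. Pooling pixels, rather than averaging
column-level CVIs, weights every pixel equally and guarantees exact
conservation: LA + SA equals the cell's choroid pixel count times the
pixel area. CT uses the real-valued (sub-pixel) boundary curves; pixel
counting uses the integer rows strictly between them.

Quality control follows the acquisition protocol: B-scans below 15 dB
(strictly; 15.0 passes) are excluded, and a volume with more than two
excluded scans is rejected outright. Excluded scans leave their grid
rows invalid — never zero.

## Group differences and their statistics

Per cell, each group is summarised by the median over eyes with a valid
cell, and the difference is the symmetric percent change
100·(x − c)/((x + c)/2). The raw form 100·(x − c)/x is provided for
comparison but unbounded as the denominator shrinks; the symmetric form
is antisymmetric under group swap and bounded in (−200, 200), which is
why it is the default for topographic difference maps.

* **Global**: each eye reduced to the median over its valid cells;
  paired Wilcoxon signed-rank across matched eyes (zero differences
  dropped first, exact distribution for ≤ 25 informative pairs; an
  unmatched comparison falls back to the rank-sum test with a warning).
  The median and IQR of per-pair symmetric percent changes are reported
  alongside, matching median [IQR] reporting.
* **Rings**: Kruskal–Wallis across the four ETDRS rings on per-cell
  values, testing whether change varies by ring. An all-identical map
  returns p = 1 by convention.
* **Sectors**: one-sample Wilcoxon of each sector's cell values against
  zero, Holm-corrected across the 13 sectors (no correction is named in
  typical sector reports; Holm controls the family-wise error without
  independence assumptions). Sectors with fewer than 5 valid cells are
  excluded and flagged.
* **Eccentricity**: cells binned at 0.05 mm by the eccentricity of
  their centre; per-bin medians regressed on bin centres with OLS at
  degree 1 and 2, bins equally weighted. The quadratic never has lower
  R² than the nested linear model, so the quadratic is *chosen* only
  when it gains more than 0.01 R²; otherwise the simpler model is
  reported. Model features — the linear x-intercept (sign-change
  eccentricity), the quadratic vertex and any in-range roots — are
  computed at full precision and rounded to 0.1 mm only at the
  reporting layer.
* **Metric coupling**: Spearman rank correlation between two difference
  maps, by default on per-bin medians (matching how eccentricity
  profiles are presented), optionally per cell.
* Shapiro–Wilk is available to justify the nonparametric reporting; it
  never switches a test silently.

A caveat the cell-level tests inherit from the design: the per-sector
one-sample test treats cells as independent. Any *shared* between-eye
shift (a handful of eyes drawn per group) correlates all cells of a map,
and with thousands of cells even a tiny shared offset becomes
"significant". The sector tests are therefore calibrated — and verified —
against cell-level noise; with strong between-eye variance and few eyes
their per-sector p-values overstate certainty. The global paired test
does not have this problem, and the test suite verifies its calibration
under between-eye variation directly.

## The synthetic generator as oracle

Every stage is tested against macular cubes with known ground truth.

**Image level.** A scene defines smooth RPE depth and CT fields (defaults
700 µm and 280 µm, flat), a bimodal choroid texture — stroma at grey
level 180, lumen ellipses at 60, semi-axes drawn from 15–50 µm, the
caliber range of small-to-medium choroidal vessels and below the cell
size so the areal fraction is controllable per cell — plus vertical
shadow bands (width 5 columns, attenuation 0.5) and additive Gaussian
noise (SD 20 grey levels, clipped to [0, 255] and rounded). Lumen
ellipses are placed by rejection sampling, independently within each
120-µm column chunk, until the realised areal fraction is within ±0.01
of the target; overlap is allowed and the fraction is measured on the
union mask, because the areal fraction — not the vessel count — is what
CVI measures. After repeated rejections the sampler shrinks toward the
small end of the vessel range (bounded at a quarter) so the last pixels
can be topped up; targets unreachable at the minimum vessel size fail
explicitly. The per-chunk construction makes the per-cell truth match
the target everywhere, which is what permits cell-level recovery bounds.
Per-pixel labels (retina / shadow / stroma / lumen / sclera) partition
the image, and per-cell truth CT/LA/SA/CVI are derived from the same
band conventions as the pipeline, so noiseless runs must agree exactly,
not approximately. The default lateral sampling is 512 A-scans per
B-scan (16.8 µm); tests use 96–256 to stay fast, and the acceptance
checks run at the full protocol scale.

**Cohort level.** Group studies need tens of eyes, so cohorts are drawn
at grid level: each control eye is `baseline × exp(eye effect + cell
noise)`, with eye-level and cell-level variation multiplicative
log-normal (3% and 6% by default) — positivity is guaranteed, which the
percent-change denominator requires. Case eyes are additionally scaled
per cell by the ratio ρ = (2 + d)/(2 − d), d = profile(r)/100, which
makes the *true* symmetric percent change between group-median cells
equal the prescribed effect profile at that cell's eccentricity. The
profile is evaluated at the centre of each cell's 0.05-mm bin — the
resolution of the eccentricity analysis — so the embedded truth is
exactly representable: with noise off, the binned regression recovers a
polynomial profile to machine precision, and any residual error in
noisy runs is attributable to noise, not to discretisation bias of the
oracle itself. Without independent cell noise a null difference map
would collapse to a single shared constant (both groups share their eye
draws across all cells), so cell noise is part of the generator's model;
the within-eye spatial covariance of real choroids is not modelled, and
cohort draws are independent across cells given the eye effect.

What the generator does *not* emulate: anatomically realistic retinal
layers, drusen or reticular pseudodrusen lesions, speckle with realistic
spatial correlation, scanner-specific intensity transfer curves, or
fovea decentration (the synthetic fovea is fixed at the volume centre;
real-data fovea offset is a metadata field). Passing tests therefore
demonstrate correctness of the measurement and inference machinery under
a controlled bimodal texture, not performance on patient images.

## Numerical conventions and edge cases

* Band membership: row *i* belongs to the choroid band iff
  floor(rpe) < i ≤ floor(csj); CT itself uses the real-valued curves.
* Median-cut ties: a split never leaves a side empty (pixels equal to
  the median move to whichever side keeps both nonempty), so exact
  bimodal bands separate exactly at any fraction.
* Inverted boundaries (csj < rpe) invalidate the column with a reason
  code; an empty band at every column is an error.
* The half-open grid: coordinate +3600 µm is outside; the 61st B-scan
  of the default protocol sits exactly on that edge and contributes to
  no cell, so 61 scans cover the 60 grid rows.
* ETDRS quadrant boundaries lie on the 45° diagonals; points exactly on
  a diagonal join the horizontal (nasal/temporal) quadrant. This
  tie-break is mirror-symmetric, so OD and mirrored OS labels agree
  *everywhere*, including at grid-cell centres that fall exactly on the
  diagonals.
* All randomness flows from one seed through per-stage derived streams;
  identical seeds give bit-identical volumes, cohorts and pipeline
  outputs (CSV/JSON byte-for-byte).

## Problem sizes used in verification

The bundled checks run at desk scale, chosen to finish in minutes while
preserving the protocol geometry: single full-protocol volumes
(61 × 462 × 512) for grid coverage and CVI recovery; 20 seeded
replicates of 40-vs-40-eye cohorts for quadratic profile recovery
(each coefficient within ±15% in ≥ 90% of replicates, quadratic chosen
in all); 100 seeded null cohorts of 10 eyes per group for calibration of
the global test (≤ 10% rejections at α = 0.05) and of the Holm-corrected
sector tests (≤ 5% significant). Cohort-level magnitudes reported from
real populations of dozens of eyes per group are not reproduced by these
synthetic runs; the synthetic cohorts verify *recovery* of embedded
effects, not the clinical effect sizes themselves.

## Limitations

* Boundary segmentation quality is assumed; errors in the input curves
  propagate directly into CT and the band used for binarization.
* The binarizer presumes a predominantly bimodal band; choriocapillaris-
  scale structure below the pixel size is not resolved.
* Sector-level inference on difference maps is descriptive when
  between-eye variance is large relative to the number of eyes (see
  above); eye-level mixed models would be the inferentially safer, and
  heavier, alternative.
* Transverse magnification is not corrected for axial length; CVI, as a
  ratio, is the metric least affected.
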