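---
title: "Vineyard canopy characterisation from multispectral vigour maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vineyard canopy characterisation from multispectral vigour maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinecanopy)
```

## The problem

Pesticide dose in vineyards should be matched to the canopy that will
intercept it. The officially recognised dose-expression parameters for
vertically trained hedgerows are the leaf wall area,

$$\mathrm{LWA} = \frac{2\,H \times 10\,000}{d_r} \quad [\mathrm{m^2\,ha^{-1}}],$$

and the tree row volume,

$$\mathrm{TRV} = \frac{H\,W \times 10\,000}{d_r} \quad [\mathrm{m^3\,ha^{-1}}],$$

with $H$ the canopy height (m), $W$ the canopy width (m) and $d_r$ the row
spacing (m). Measuring $H$ and $W$ by hand across a parcel is slow, which
blocks variable-rate application in practice. This package implements and
tests a remote-sensing alternative: NDVI-based vigour maps from
fine-resolution (UAV-scale, ~6.5 cm) and coarse-resolution (satellite-scale,
3 m) multispectral imagery, per-vine feature extraction over a systematic
sample of vines, and log-linear regressions that translate the
remote-sensing variables into $H$, $W$, LWA and TRV.

Because the field campaigns this methodology comes from are not publicly
deposited, the package ships a synthetic vineyard scene generator that
reproduces the statistical structure the analysis assumes, so every step is
testable end to end.

## The mapping procedure

For fine-resolution imagery the chain is:

1. **NDVI** per pixel, $(NIR - R)/(NIR + R)$.
2. **Canopy segmentation** by an NDVI threshold. The original field
   workflow chose the threshold per flight by visual inspection; since that
   is irreproducible, the default here is Otsu's bimodal histogram split
   (`segment_canopy(ndvi, "otsu")`), with a numeric override for manual
   thresholds.
3. **Masking**: background pixels are set to NDVI 0 (a value, deliberately
   distinct from the missing-data marker used for zero-denominator pixels).
4. **IDW interpolation** of the canopy pixels' NDVI onto the full grid,
   giving a continuous vigour surface. Value at a cell is
   $\sum w_i v_i / \sum w_i$ with $w_i = d_i^{-p}$ over the $k$ nearest
   canopy anchors.
5. **Quintile zoning**: the P20/P40/P60/P80 percentiles of the in-plot
   cells split the surface into low (< P20), medium and high (> P80)
   vigour — a 20/60/20 split by construction.

At 3 m resolution the pixel is wider than the row spacing, so canopy cannot
be separated from soil; the raw NDVI grid is classified directly
(`satellite_vigour()`), exactly as coarse-scale practice dictates.

Per sampled vine, a rectangle 1.2 m along the row by one row spacing across
(`vine_polygon()`) delimits extraction: the mean NDVI of canopy cells
(`NDVI_D`), the pixel-counted projected canopy area (`Prj_area_D`), their
product (the composite UAV predictor), the majority vigour class, and at
coarse scale the overlap-area-weighted NDVI (`NDVI_S`). Vines whose polygon
centroid lies within 3 m of the plot border are flagged `Edge_pnt`, because
3 m pixels there mix in adjacent land cover.

## The regression core

`gated_lm()` is the modelling centrepiece: ordinary least squares on
log-transformed variables,

$$\ln(\mathrm{response}) = a + b \,\ln(\mathrm{predictor}) + \varepsilon,$$

followed by a residual-normality gate. If a Kolmogorov–Smirnov test of the
residuals rejects at $\alpha = 0.05$ the model's verdict is `rejected` and
it should not be used for prediction; otherwise `accepted`. The returned
object carries the `lm` fit and supports `print`, `summary`, `coef`,
`predict` (including 95% confidence bands, as drawn by `plot`), and
`residuals`.

Two analysis modes mirror how the data can be read:

* **SPD** (single-point data): every vine-date record is one point.
* **AD** (aggregated data): records are first averaged within
  (plot, year, stage, vigour class) cells — three zone means per plot and
  date — and the regression runs on the cell means. Averaging suppresses
  within-class noise, so AD fits are typically stronger; the acceptance
  suite verifies this pattern on simulated fields.

Satellite analyses default to edge-rejected records, after the Spearman
with/without-edge comparison (`edge_sensitivity()`) shows border
contamination depresses the NDVI-to-structure correlations.

## What the synthetic generator emulates

* **Layout**: parallel rows 2.2–2.8 m apart, vines every 1.2 m, anchored
  half a spacing inside the plot boundary; the default 22 m × 12 m plot
  holds a 10 × 10 grid.
* **Vigour surface**: a linear trend across the plot plus 2–4 Gaussian
  bumps plus iid noise, clamped to [0, 1]. The reference methodology only
  states that plots contain low/medium/high zones; this is the simplest
  generative model with that property. Defaults: base 0.5, trend amplitude
  0.3, 3 bumps of amplitude 0.25 at 8 m length scale, noise sd 0.05.
* **Canopy dimensions**: affine in vigour (height 0.4–0.9 m, width
  0.2–0.45 m at the first stage), multiplied by a stage scale of 1.0 at
  BBCH 59 and 1.5 at BBCH 75 and 81 — the 1.5× growth-then-plateau pattern
  canonical for the crop. The same seed drives all stages, so the spatial
  vigour pattern is a fixed property of the plot.
* **Reflectance**: canopy red and NIR are affine in vigour
  ($R = 0.10 - 0.06v$, $NIR = 0.40 + 0.30v$, i.e. noiseless canopy NDVI
  0.60–0.89); soil, weed, shadow and road surfaces are constants chosen so
  canopy is strictly separable (soil NDVI 0.15, weeds 0.36, road 0.03).
  Gaussian noise (sd 0.01 reflectance) is added and truncated to [0, 1] —
  truncation rather than resampling, whose bias is negligible at this noise
  level. Canopy footprints are rectangles, matching the hedgerow training
  system and keeping the projected-area truth analytic.
* **Two resolutions**: the fine grid uses the 0.0648 m ground sample
  distance implied by the reference camera geometry (95 m altitude, 5.5 mm
  focal length, 3.75 µm pixel pitch; see `gsd()`); `degrade_to_satellite()`
  aggregates to 3 m by exact area-weighted block means, which produces the
  coarse-scale spectral mixing naturally.
* **Edge contamination** is mechanistic, not a dial: the raster extent pads
  the plot with 6 m of road surface, so 3 m border pixels mix road signal
  in the same way adjacent roads contaminate real satellite pixels.

What it does **not** emulate: radiometric calibration error, orthomosaic
stitching artefacts, BRDF/sun-angle effects, terrain slope, within-canopy
gaps, weather-driven growth variation, and real spectral response
functions. Tests passing on these scenes therefore demonstrate the
correctness and internal consistency of the pipeline, not the field-level
accuracy of any specific sensor.

## Numerical and design choices

* **Coordinates**: one projected metric CRS throughout, north-up rasters,
  origin at the top-left pixel corner, 1-based matrix indexing. No
  reprojection is ever attempted; mismatched CRS labels are an error at the
  I/O boundary.
* **Raster format**: 32-bit float TIFF with a JSON georeferencing sidecar;
  NDVI is affinely rescaled to [0, 1] for storage and a validity plane
  preserves missing cells, so grids round-trip within 1e-6.
* **Quintiles** use the standard linear-interpolation percentile
  (`quantile` type 7), computed per plot per date; values exactly at P20 or
  P80 are medium (the outer classes are defined by strict inequalities).
  A constant surface classifies everything medium, with a warning.
* **IDW defaults** $p = 2$, $k = 12$, output cell = input cell — none are
  prescribed by the source methodology; $p = 2$ is the near-universal
  default, and $k = 12$ keeps the interpolation local at a few tens of
  centimetres between canopy anchors. The k-nearest-neighbour search runs
  in compiled code on a bucketed spatial hash; a cell coincident with an
  anchor returns the anchor value exactly.
* **Vigour-class assignment** of a vine is the majority class of its
  canopy cells, ties resolved to medium (the assignment rule is not
  specified upstream; majority is the natural estimator and medium the
  conservative tie-break).
* **Cell membership** is centre-in-polygon at fine resolution (pixelisation
  error is bounded by the 6.5 cm cell) but exact rectangle-clipping area
  weights at 3 m, where a vine polygon is a fraction of one pixel.
* **Edge rule** uses the polygon centroid, treating a vine as a point-like
  sampling unit; the comparison is strict (`distance < 3 m`).
* **Normality gate**: one-sample KS against a normal with mean and sd
  estimated from the residuals. Estimating parameters makes plain KS
  conservative (the Lilliefors issue); `gate = "lilliefors"` switches to
  the corrected test (via the nortest package). The verdict is a pure
  function of the p-value and $\alpha$.
* **Pooling**: SPD and AD fits pool plots, years and stages into one model
  per response; per-subset fits can be run by filtering the record table.
  Both axes are log-transformed. No multiple-testing correction is applied
  across the four responses; all p-values are reported.
* **Log domain**: `ln_transform()` refuses non-positive values and lists
  the offending records rather than dropping them silently. With the
  default reflectance model all NDVI-derived predictors are positive;
  degenerate vines (no canopy pixels) yield missing records, which the
  analyses drop with an explicit warning.

## Problem sizes

The package's desk-scale defaults — one 22 m × 12 m plot, 100 vines, three
stages, 25 sampled vines (75 records), ~63 000 fine-resolution cells — were
chosen so a full `run_pipeline()` takes a few seconds and the complete test
suite a few minutes, while every statistical behaviour of interest (growth
ratio, AD-over-SPD improvement, amplitude compression at 3 m, edge effects)
is already expressed at this size. Larger plots are a matter of
configuration, not code.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(default_config(seed = 1), outdir = "vc_out")
print(res$analysis)          # Spearman matrices + SPD/AD regression tables
plot(res$maps$BBCH75$uav$map)   # three-class vigour zoning
plot(res$analysis$spd_uav$TRV_M) # Ln TRV vs Ln composite, with 95% band
```

## Known limitations

* Vector geometry is limited to the shapes the pipeline needs (convex
  vine rectangles, simple plot polygons); it is not a general GIS.
* The satellite path inherits whatever georeferencing the fine scene has;
  co-registration error between platforms is not simulated.
* The normality gate tests one model assumption only; an `accepted` verdict
  is not a certificate of predictive validity.
* AD regressions at desk scale rest on few aggregated points (9 cells);
  their R² is accordingly volatile across seeds. The acceptance checks
  therefore assert qualitative orderings across many seeds, not single-run
  values.
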