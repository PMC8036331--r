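# vinecanopy

Canopy characterisation for vineyards from multispectral remote sensing —
for agronomists and precision-viticulture engineers who need per-zone
canopy structure (height, width, leaf wall area, tree row volume) to drive
variable-rate pesticide application, without measuring every vine by hand.

## What it computes

The two officially recognised dose-expression parameters for vertically
trained hedgerow vineyards are

    LWA = 2 · H · 10000 / d_r        [m² ha⁻¹]   (leaf wall area)
    TRV = H · W · 10000 / d_r        [m³ ha⁻¹]   (tree row volume)

with canopy height `H` (m), width `W` (m) and row spacing `d_r` (m). The
package links these to remote sensing through the chain

1. **NDVI** `(NIR − R)/(NIR + R)` from 5-band UAV-scale (~6.5 cm/pixel) or
   4-band satellite-scale (3 m/pixel) reflectance rasters;
2. **vigour mapping**: canopy segmentation (Otsu or manual NDVI threshold),
   masking, inverse-distance-weighted interpolation to a continuous
   surface, and quintile zoning into low (< P20) / medium / high (> P80)
   vigour classes — the satellite path classifies raw NDVI directly, since
   a 3 m pixel cannot be segmented;
3. **per-vine extraction** over a systematic uniform random (SUR) sample:
   mean canopy NDVI (`NDVI_D`), projected canopy area (`Prj_area_D`), their
   product as the composite UAV predictor, area-weighted satellite NDVI
   (`NDVI_S`), vigour class, and an edge-point flag for vines within 3 m of
   the plot border;
4. **gated log-linear regression** `ln(response) = a + b·ln(predictor) + ε`,
   accepted only if a Kolmogorov–Smirnov test cannot reject residual
   normality, fitted in single-point (SPD) and vigour-class-aggregated
   (AD) modes, plus Spearman correlation matrices with and without edge
   points.

A synthetic vineyard scene generator (row layouts, smooth spatial vigour,
soil/weed/shadow/road background, both resolutions with exact area-weighted
degradation) provides ground truth for testing and simulation, since the
field data the methodology was developed on are not publicly deposited.

## Worked example

```r
library(vinecanopy)

lwa(0.78, 2.2)          # 7090.909  m² ha⁻¹ for a 0.78 m canopy at 2.2 m rows
trv(0.78, 0.33, 2.2)    # 1170      m³ ha⁻¹ adding a 0.33 m canopy width

res <- run_pipeline(default_config(seed = 1), outdir = "vc_out")
res$analysis$spd_uav$TRV_M
#> SPD model [accepted]: Ln TRV_M ~ Ln NDVI_D_x_Prj_area_D
#>   slope 1.7262, intercept 8.9509, R2 0.919, KS p 0.0935, n 75
```

The run simulates one 22 m × 12 m plot (100 vines, three growth stages,
25 SUR-sampled vines), maps vigour at both resolutions, extracts 75 vine
records and fits all models. The SPD line above says: across vine-dates,
log TRV rises with the log composite predictor with R² 0.92, and the
normality gate accepts the model (p = 0.094 > 0.05). Aggregating into
vigour-class means strengthens the fits:

```r
as.data.frame(res$analysis$ad_uav)[c("response", "r_squared", "verdict")]
#>       response r_squared  verdict
#> H_M        H_M 0.9711857 accepted
#> W_M        W_M 0.9782509 accepted
#> LWA_M    LWA_M 0.9711857 accepted
#> TRV_M    TRV_M 0.9754387 accepted
```

and rejecting edge points raises the satellite NDVI–TRV rank correlation
(0.49 → 0.64 in this run), the border-contamination pattern that motivates
edge filtering:

```r
res$analysis$edge$with_edges$rho["NDVI_S", "TRV_M"]     # 0.493
res$analysis$edge$without_edges$rho["NDVI_S", "TRV_M"]  # 0.637
```

`vc_out/` holds the vine-record CSV, regression CSV, vigour/NDVI rasters
(float TIFF + JSON georeferencing sidecars), GeoJSON layouts and a JSON
report; reruns with the same config are byte-identical. A thin CLI wraps
the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "vinecanopy.R", package = "vinecanopy"))') \
    run-all --out vc_out --seed 1
```

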