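---
title: "Refining niche models with nichecarve: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining niche models with nichecarve: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecarve)
```

## The problem

An environmental niche model maps climatic covariates to a continuous
habitat-suitability surface — the species' *potential* distribution. The
*realized* distribution is smaller: soils, land use, dispersal and history
exclude areas that climate alone would permit. `nichecarve` closes part of
that gap by post-processing the ENM raster with information the ENM never
saw: edaphic/land-cover filters and a high-resolution land class model (LCM),
and by comparing baseline with projected-climate suitability to map *temporal
corridors* — where a population can persist in place under climate change.

All inputs are ESRI ASCII grids in geographic coordinates. Every input except
the LCM must share extent and resolution exactly (column/row counts compared
exactly, float header fields to a relative tolerance of 1e-9, since different
GIS write different trailing digits). The LCM may be finer and smaller, as a
30-m land cover product is against a 30-arc-second climate surface. Inputs in
projected coordinate systems (e.g. an Albers-projected land cover product)
must be reprojected to latitude/longitude beforehand; the package does no
reprojection and reads no CRS metadata.

## The pipeline

**Thresholding.** A cell is climatically suitable when its suitability
*exceeds* the threshold, read strictly (`value > t`); `strict = FALSE`
switches to `>=` because the convention at the exact boundary is not
standardized. The threshold conventionally used with this workflow is the
mean of two MaxEnt evaluation thresholds, e.g.
`compute_threshold_average(0.088, 0.473) = 0.2805` in the Fraser fir case
study. Baseline and projected thresholds may differ; the case study uses one
value for both. Nodata cells are never suitable.

**Feature filtering.** Up to three feature rasters trim the mask. Categorical
features keep cells whose class code is in an accepted set; continuous
features keep cells whose value lies in any of a list of closed intervals
(endpoints inclusive). Feature nodata *fails* the filter — absence of
evidence of suitability is treated conservatively. A feature applies to one
or both climate phases; against a mask of a phase it does not cover, it is a
no-op. Filtering is monotone: adding a filter never adds area.

**Corridors.** Two masks classify each cell as 0 (unsuitable), 1 (baseline
only), 2 (both climates), 3 (projected only). Swapping the two inputs swaps
codes 1 and 3 and fixes 0 and 2.

**Merge into the LCM.** The corridor is coarse; the LCM is fine. Each LCM
cell whose class is *valid* (user-chosen, e.g. forest classes 41/42/43)
samples the corridor code at its own cell center by nearest-by-center point
lookup. Categorical codes cannot be interpolated, and area-weighting would
invent mixed classes, so point lookup is the simplest defensible projection;
the result is deliberately a *pseudo* high-resolution product — corridor
boundaries remain coarse even though cells are fine. Codes 1–3 relabel the
cell `highest + code`, where `highest` defaults to the maximum class observed
in the file (reproducible from the input alone; a nominal class-table maximum
can be supplied instead). In the Fraser fir example NLCD's highest class is
95, so the synthetic classes are 96/97/98. A baseline-only run (no projected
ENM) merges a {0,1} corridor, producing only `highest+1`. The merge changes
labels only: geometry, cell count and the nodata pattern are conserved, which
is why the grand total area of the merged product is invariant across model
variants. Collisions (`highest+1..3` hitting an existing class or the nodata
sentinel) abort the run.

A cell center falling exactly on a coarse-grid edge goes to the south/east
(larger-index) cell — an arbitrary but fixed tie-break; for exactly nested
grids (an integer refinement factor) centers never hit edges.

## Quantification and areas

Per-class cell counts and areas are computed globally and per tile. Cells in
one grid row share a latitude band, so a cell's exact spherical area is

$$A = R^2 \, \Delta\lambda \, (\sin\varphi_{top} - \sin\varphi_{bot}),$$

with $R$ = 6371.0072 km. The radius is the authalic one — the sphere with the
Earth ellipsoid's surface area — because it minimizes total-area error in a
spherical formula; it is configurable. The whole-sphere limit ($4\pi R^2$)
and agreement with midpoint-rule numeric integration to 1e-6 relative are
asserted in the test suite. The default "band" mode applies this formula per
row; an "average" compatibility mode multiplies class counts by the
raster-wide mean cell area, matching tools that report a single average cell
size (the case-study report quotes one mean cell width × height). Both modes
give identical grand totals.

Tiles (≤ 225) partition the raster's bounding box into equal rectangles,
numbered row-major from the north-west corner. Cells are assigned by center,
with the same south/east tie-break, so every non-nodata cell lands in exactly
one tile and per-class tile sums equal global totals exactly. Nodata cells
are excluded from class rows and reported separately — class 0 is a real
class (e.g. "unclassified" or corridor "unsuitable") and must not be
conflated with nodata. Reports are CSV (metadata block, per-class rows with
per-tile columns, totals row); the tile grid is GeoJSON.

## Synthetic fixtures

`fixture_spec()` describes a deterministic toy landscape mirroring the case
study's scale ratios at test size: a 40×40 ENM at 0.05° over a 2° window in
the southern Appalachians, with the LCM refined 5× (200×200). Suitability
surfaces are radial Gaussian bumps (peak 1 at the niche center), so the
suitable disc at threshold $t$ has known radius $r\sqrt{2\ln(1/t)}$ and
corridor code regions are known analytically; the default centers are offset
so that codes 1, 2 and 3 are all non-empty at the 0.2805 threshold. Features
are vertical class bands (exact per-class counts) or a planar gradient; the
LCM is a seeded random NLCD-like mosaic with class 95 always present, so
merges land on 96/97/98. All randomness derives from the single `seed` field
and identical specs generate identical rasters.

What the fixtures deliberately do not emulate: spatial autocorrelation of
real land cover, ENM calibration error, mismatched ENM/LCM extents, and
projected-coordinate inputs. Tests passing on fixtures therefore validate
the *arithmetic and bookkeeping* of the pipeline, not any ecological claim
about a real species.

## Numerical and design choices

- Row order follows the ASCII grid file: row 1 is the northernmost, and all
  row↔latitude arithmetic is written against that order to avoid silent
  flips.
- Grids are square-celled (`dx = dy = cellsize`); rectangular-cell dialects
  are rejected. Center-form headers (`xllcenter`) are normalized to corner
  form on read. A missing `NODATA_value` defaults to −9999 with a warning.
- Categorical rasters are validated to integer cell values and serialized as
  integer tokens.
- The worked-example arithmetic in the acceptance checks uses the published
  per-class area tables as *inputs* (shipped as CSV), since the original
  MaxEnt/PRISM/STATSGO/NLCD rasters cannot be rebuilt at desk scale; the
  synthetic pipeline exercises the same code paths end to end. Test problem
  sizes (50×50 oracle grids, 100 seeded property fixtures, 200×200 LCM
  merges) were chosen to keep the whole suite under a minute while covering
  every operation.
- The percentage declines printed in the case study round from 16.76% and
  91.38%; the package reports the unrounded values.

## Limitations

- No reprojection, no GeoTIFF/shapefile I/O, no CRS metadata; inputs must be
  prepared in a GIS.
- Point-lookup merging inherits the ENM's effective resolution; fine-scale
  corridor boundaries are artifacts of the LCM grid, not added information.
- The spherical area formula ignores the ellipsoidal flattening beyond what
  the authalic radius absorbs (relative error < 0.3% at mid-latitudes).
- Masks, corridors and merges are single-threaded whole-matrix operations;
  very large rasters are bounded by memory, not CPU.
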