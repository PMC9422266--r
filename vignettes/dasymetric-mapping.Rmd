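---
title: "Impervious-surface dasymetric population mapping: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impervious-surface dasymetric population mapping: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugli)
```

## The model

Dasymetric mapping redistributes counts published for coarse areal units
onto a finer grid using an ancillary covariate as the weight. Here the
units are census block groups with populations $P_g$, the grid is 30-m
pixels in a projected equal-area CRS, and the covariate is the impervious
surface fraction $w_i \in [0,1]$ after *residential masking*. Each pixel
receives

$$p_i = P_g \, \frac{w_i}{W_g}, \qquad W_g = \sum_{i \in g} w_i,$$

so pixel estimates are fractional persons per 900 m² cell and every zone's
pixels sum back to $P_g$ exactly — the mass-preserving (pycnophylactic)
property. That conservation contract is the method's defining invariant:
aggregated to the block group or any union of block groups, the gridded
product reports the identical population as its census input.

The underlying behavioural assumption is that, once non-residential
impervious surfaces are removed, population within a block group is
proportional to the amount of impervious cover in each pixel. The masking
rules implement "non-residential":

1. **Low-cover filter.** Fractions $\le$ `low_threshold` become 0. The
   default is 0.01 — at most 1 % of the pixel's area impervious — and the
   comparison is deliberately *inclusive*: 0.01 itself is removed, 0.0101
   is kept. The threshold is applied on the fraction scale; the reader
   converts the common 0–100 integer-percent dialect
   (`scale_mode = "percent_0_100"`) before any rule runs.
2. **Road removal.** Pixels whose descriptor class is in `road_classes`
   become 0. The default set `c(1, 2, 3)` covers the primary, secondary
   and tertiary *urban* road codes of the 2016 descriptor legend; we take
   the urban qualifier literally and retain non-urban road classes, while
   leaving the set fully configurable since legends differ between product
   releases.
3. **Zero-population blocks.** Pixels whose centre lies in a census block
   with zero population become 0 regardless of cover; such imperviousness
   is assumed commercial or industrial. Blocks are used because they are
   the finest unit with published counts. Pixels covered by *no* block are
   retained with a warning and a count in the run report: blocks should
   tile the county, and zeroing on missing data would silently delete
   population weight.

Each rule only writes zeros, so the three masks are idempotent,
value-decreasing and commute — the composed surface is independent of rule
order, which the test suite checks over all six orderings.

## Degenerate zones and the fallback

A block group can have $P_g > 0$ but $W_g = 0$ after masking (e.g. a fully
zero-population-block overlap, or no mapped impervious cover). Proportional
apportionment is then undefined, yet conservation must hold, so
`apportion_population()` takes an explicit `fallback_mode`:

* `uniform_populated_blocks` (default): spread $P_g$ uniformly over the
  zone's pixels lying in blocks with nonzero population; if none exist,
  over all the zone's pixels. This keeps people out of provably
  uninhabited blocks while preserving the total.
* `uniform`: spread over all the zone's pixels.
* `error`: refuse to proceed.
* `drop`: leave the zone empty, warn, and record the loss in the report —
  the only mode that breaks conservation, and it does so loudly.

The fallback is this package's own design choice for a case the
proportional model leaves open; affected zones are flagged in the zone
report so they can be audited.

## Geometry conventions

Every raster–vector operation uses one membership rule: a pixel belongs to
the polygon containing its centre, polygons are closed (boundary points
belong), and a centre lying exactly on a shared boundary goes to the
lexicographically smallest `zone_id`. The rule is deterministic and cheap
to check against a brute-force point-in-polygon oracle, and because the
dasymetric and validation paths share it they cannot disagree about pixel
ownership. All inputs must already share one projected equal-area CRS; the
package validates CRS identity and refuses to reproject, because
resampling choices during reprojection would change results invisibly.

Areal overlap for the naïve baseline is computed exactly: each zone ring is
clipped against every at-risk pixel rectangle (Sutherland–Hodgman), with
shells adding and holes subtracting area. Point membership uses even-odd
ray crossing with an absolute boundary tolerance of $10^{-9}$ map units —
negligible against 30-m pixels.

## Hazard validation

Hazard rasters are binarized first: wildfire classes in `at_risk_classes`
(default medium/high/very high out of five) are at risk; flood pixels are
at risk iff water surface elevation is strictly positive; nodata is never
at risk, since absence of hazard evidence must not create exposure.
Connected components of equal-valued pixels become polygons
(4-connectivity by default, 8 available; the traced boundary preserves
holes, and polygon area always equals pixel count × pixel area). Population
at risk is the zonal sum over at-risk polygons, computed on each population
raster's native grid so third-party products at other resolutions are
summed without resampling. The baseline assumes uniform density per block
group, and methods are compared as percent difference against it. When the
hazard contains no at-risk pixel the percent difference is undefined and
reported as `NA` with a warning rather than a fabricated zero.

## The synthetic county generator

`generate_synthetic_county()` emulates the structure the workflow needs —
not real demography. Rectangular blocks tile the grid (point-in-polygon
oracles stay trivial); block groups are unions of whole blocks; impervious
fractions follow a zero-inflated Beta model (defaults: 35 % structural
zeros, Beta(1.2, 3) otherwise — mostly sparse cover with occasional dense
development); road corridors are painted into the descriptor; a configured
share of blocks (default 15 %) is forced to zero population. Ground truth
is placed proportionally on the *post-mask* surface, and block / block
group populations are aggregates of that truth, so the pipeline's
assumptions hold exactly and the full pipeline must recover truth to
$\le 10^{-9}$ relative per-pixel error — a sharp end-to-end correctness
check. Setting `misspecified = TRUE` moves 2 % of people onto masked
pixels, which recovery reporting must then surface as nonzero error.

What passing these tests does **not** show: that real populations are
proportional to impervious cover, that real block geometries (concave,
multipart, sliver-ridden) are handled with survey-grade robustness, or how
the method behaves under misregistered or reprojected inputs. The fixtures
validate the machinery, not the behavioural assumption.

Default problem sizes are desk-scale by design: 48 × 48-pixel counties
with 64 blocks in 16 block groups, oracle comparisons on grids up to
32 × 32, and 1000 randomized zones for the conservation property. These
sizes exercise every code path while keeping the suite fast.

## Numerical choices

* Pixel populations stay fractional; accumulation is in double precision.
  Observed conservation residuals are at the $10^{-13}$ level, far inside
  the $10^{-6} \cdot \max(1, P_g)$ tolerance asserted by the tests.
* Nodata impervious pixels are treated as fraction 0 (uninhabitable) with
  a logged count, consistent with the zero-assignment for absent cover.
* Output rasters are written at full precision (`%.17g`), making reruns
  byte-identical and write-then-read round-trips bit-compatible.
* Results are independent of zone processing order by construction: zones
  are independent given the weight layer, mirroring county-parallel
  production designs as a contract rather than a concurrency mechanism.

## File formats

Rasters are Esri ASCII grids with a `.prj` sidecar carrying the CRS
identifier — a plain-text format that stores the full geotransform, which
keeps fixtures and outputs inspectable and diffable. Vector zones are
GeoJSON with configurable `zone_id` / `population` attributes. The nodata
convention of written population rasters is configurable (default −9999)
rather than guessed.

## Known limitations

* No reprojection, no geographic (degree-unit) CRS support, and no
  download clients: inputs must be prepared in one equal-area CRS.
* Hazard polygons must originate from `polygonize_binary()` (they carry
  their source pixels); arbitrary external risk polygons are out of scope.
* The areal-weighting clip assumes valid simple rings with GeoJSON ring
  roles (first ring shell, rest holes).
* County-code harmonization ships the two known 2010→2016 corrections
  (Shannon→Oglala Lakota rename, Bedford city-into-county merge) as
  configuration; other vintage pairs need their own map.
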