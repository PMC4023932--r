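---
title: "Spatial analysis of a digitised butterfly collection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial analysis of a digitised butterfly collection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicmaps)
```

`mimicmaps` characterises a georeferenced museum collection in space. This
vignette is the package's own account of the statistics it implements, the
choices made where the design was genuinely open, and what its calibration
on synthetic data does and does not establish about real collections.

## The data model

A specimen record is one pinned voucher: id, sex, female wing-pattern morph
(males carry none in this system), morph group, subspecies, country, verbatim
locality, decimal coordinates, and a geocode error in km. Validation enforces
unique non-empty voucher ids (duplicates are a hard error), both-or-neither
coordinates, and non-negative errors; a morph on a non-female record is a
warning rather than an error, because historic labels are messy and the
record may still be informative.

The morph registry encodes the controlled vocabulary: eleven recognised
subspecies with their documented female-morph lists, their assignment to the
Western/Eastern mainland lineages or the Indian Ocean islands, nine groups of
similar-looking forms, and the fixed set of "imperfect" mimic forms
(`trimeni`, `dorrippoides`, `dionysoides`, `proto-cenea`, `mixtoides`,
`swynnertoni`, `carpenteri`, `lamborni`) plus the label `intermediate` used
for specimens combining attributes of more than one group. Two reconstruction
choices deserve note. First, the published subspecies table spells one form
`hippcoonides` in a single row; the registry stores the corrected
`hippocoonides`, the spelling used everywhere else. Second, the full
morph-to-group map is only partially fixed by the text (the hippocoon group
comprises `hippocoon`, `hippocoonides` and `meseres`; `leighi` sits in the
planemoides group; tailed Ethiopian variants belong with their untailed base
forms); the remaining assignments follow form-name affinity and are the
package's own reconstruction — analyses that depend only on the imperfect
set, the subspecies lists, or group *existence* are unaffected.

Label normalisation (lower-case, strip the "f." forma prefix and typographic
emphasis, collapse whitespace) is applied on both sides of every registry
lookup, so `"f. Trimeni"` and `"trimeni"` agree.

## Geocode filtering

`filter_geocoded()` keeps records whose positional error is strictly less
than `max_error_km` (default 40 km, the gazetteer-matching accuracy cut under
which the collection was geocoded). The inequality is deliberately strict: an
error of exactly 40 km is excluded. Records with coordinates but no recorded
error are treated as unverified and dropped. The filter is idempotent and
monotone in the threshold, and both properties are tested.

## Projection

All distances and areas are computed in a spherical Albers equal-area conic
projection on the authalic sphere (R = 6371007.181 m) with the conventional
Africa parameters: central meridian 25°E, standard parallels 20°N and 23°S,
latitude of origin 0°, no false easting/northing. The exact parameterisation
is a documented convention, not a fact of the source workflow, and is
configurable (`albers_africa()`); the `crs_tag` records it on every projected
object. Two numerical points: with standard parallels straddling the equator
the cone constant n is negative, and the inverse mapping applies the standard
sign reversal of x, y and rho0 before recovering the angular coordinates; and
because the projection is exactly equal-area on the sphere, projected polygon
areas agree with spherical-excess areas to well under 0.5% (tested against a
closed-form oracle). Distances after projection are planar Euclidean, not
geodesic, matching a projected GIS workflow.

## Spatial weights

Neighbourhoods are binary closed distance bands: w_ij = 1 when
0 < d(i,j) ≤ band. Coincident localities are neighbours. Gi* uses
self-inclusive weights (w_ii = 1); Moran's I excludes self-pairs. Weights are
symmetric and monotone in the band, both asserted as properties.

## The analysed attribute and the locality

Specimens are aggregated to unique collection localities (projected
coordinates rounded to 1 m) carrying the specimen count as the analysed
value. The rounding tolerance only collapses sub-metre numerical noise; real
distinct sites are never 1 m apart in geocoded museum data.

## Moran's I, band selection

`morans_i()` implements the textbook statistic with the randomisation-
assumption variance (the common GIS default; the normality variance is
available behind a flag), using the binary-symmetric shortcuts S1 = 2W and
S2 = 4 Σ deg². Its z-score is validated two ways: against an independent
brute-force double-loop implementation to 1e−10 relative error, and against
an explicit 999-permutation null within 0.3 z-units. Degenerate inputs fail
loudly: constant values ("zero variance") and neighbourless weights ("empty
weights") are errors, and `incremental_moran()` skips unusable bands with a
warning, choosing the band with the highest z (ties to the smallest band).

The default band sweep runs in 10 equal steps from the smallest band at
which every locality has a neighbour up to half the maximum pairwise
distance. For the reference analysis we instead sweep the round-number bands
100–1000 km in 100 km steps (`reference_bands()`), the grid an analyst would
use at continental extent.

## Gi* hot spots: why the statistic runs on counts

`gi_star()` labels a locality hot when its z exceeds 2.5 standard deviations
(the density-outlier cut used in the collection's sampling-effort maps) and
cold below −2.5. No multiple-testing correction is applied by default — the
source workflow applies none — but `fdr = TRUE` switches to
Benjamini–Hochberg labelling.

`hotspot_pipeline()` applies Gi* to the per-locality specimen counts at the
Moran-selected band. The Gi* neighbourhood sum of counts *is* the circle
count of specimens at that scale, so this is a hot-spot analysis of the
sampling-density layer. The alternative — computing a 280 km circle-count
density value per locality first and feeding that to Gi* — was implemented
and rejected during development: a pre-smoothed attribute is strongly
autocorrelated between neighbours by construction, the permutation null
underestimates the variance of neighbourhood sums, and on completely random
data 10–20% of localities exceed the 2.5 sd cut at every band we tried. On
raw counts the same cut labels 0–3% (bounded in tests by three times the
nominal normal tail). The 280 km density surface and its 7 quantile classes
are still computed and exported — they are the heatmap product — they are
just not the Gi* input. Quantile classes are equal-frequency by rank with
ties assigned to the lower class, merging (with a warning) when fewer
distinct values than classes exist.

A locality whose neighbourhood spans the entire data set has a vanishing Gi*
numerator and denominator; its z is defined as 0 with a warning.

## Range inference

Per taxon (subspecies or morph group) with at least three non-collinear
localities: convex hull (counter-clockwise, anchored at the lowest-y vertex),
then clipping to occupied environmental classes. The class raster is used at
20 km resolution; finer rasters are block-downsampled by majority with ties
to the smallest class id (a deterministic convention). Cells are half-open,
so a point on a shared upper edge belongs to the next cell. Clipping is
exact cell-polygon geometry, not a rasterised approximation: horizontal runs
of occupied cells are merged into rectangles and each rectangle is
intersected with the (convex) hull by Sutherland–Hodgman clipping, so every
clipped part is itself convex. The invariants — clipped area ≤ hull area,
every occurrence inside the clipped polygon, idempotence of re-clipping —
are tested, the first two exactly, the last to 1e−9 relative area.

Subspecies labels must be present in the input; extending designations to
unlabelled nearby records by male wing pattern is expert judgement, out of
algorithmic scope.

## Overlay

`overlay_imperfect()` selects geocoded records whose morph is in the
imperfect set, projects them, and counts containment in the union of the
target polygons (a point in any part counts once). Containment is even-odd
ray casting with an inclusive boundary — conservative for a "collected
within the extent" claim. The counting unit is specimens, not unique
localities. Beyond the raw counts the package offers
`overlay_permutation_test()`, a label-shuffling significance test; this is an
extension beyond the source analysis and is clearly flagged as such.

## The synthetic generator and the reference scenario

`generate_records()` emulates exactly the structure the analyses assume:
collection *sites* (background uniform at complete spatial randomness,
clusters uniform in discs), 1 + Poisson specimens per site, sexing at a
configurable female fraction, female morphs drawn per containing region,
geocode errors uniform on [0, 60] km so the 40 km filter removes about a
third of records, and imperfect-morph specimens placed at a collection site
inside the transitional area with probability 1 − leak (attached to existing
sites so the locality structure is preserved), making the inside count
exactly binomial. All draws flow from one seed through a single local RNG,
leaving global state untouched.

The documented reference scenario (`reference_scenario()`) fixes the study
conditions: a 4000 × 3400 km window; three over-collected clusters of 100 km
radius with centres more than 900 km apart — so the planted spatial scale is
the 200 km disc diameter — sampled at 1 + Poisson(3) specimens per site
against 250 background sites at 1 + Poisson(0.3) (the real collection's
concentration of effort around Lake Victoria is starker still); two
transitional sub-regions (for ssp. *meseres* and ssp. *polytrophus*) whose
disjoint union hosts the imperfect forms at 30% of female draws with a leak
of 0.1, echoing the observed 14 of 145 imperfect specimens outside the
transitional extent; and a four-class 20 km raster with a central
uninhabitable arid block that no collection site can occupy but convex hulls
span — so class clipping is exercised end to end, not vacuously.

Calibration results on this scenario (recomputed by the test suite and
`scripts/acceptance.R`, never hard-coded): the Moran sweep selects the
200 km band; all planted cluster localities are labelled hot; among
background localities far enough from every cluster that their Gi*
neighbourhood cannot overlap one — the statistical null population for a
false-positive rate — none exceeds the cut, and even counting the "halo"
localities whose circles genuinely overlap a cluster, the background rate
stays in single digits. False positives are *defined* over that null
population: a locality whose neighbourhood contains planted structure has a
genuinely elevated circle count, and calling it hot is correct behaviour of
the statistic, not an error of the implementation.

What the generator does not emulate: real coastlines and irregular region
shapes, non-uniform geocode-error structure (historic labels are worse in
remote areas), temporal collecting waves, taxonomically biased collecting,
or true environmental class maps. Passing tests therefore establish that the
statistics are implemented correctly and calibrated under their own
assumptions — not that any particular real collection satisfies those
assumptions.

## Problem sizes and numerical tolerances

The test suite runs oracle comparisons at 200 localities (1e−10 relative
error against brute-force double loops), permutation checks at n = 100 with
999 shuffles (0.3 z-units), null calibration at 500 replicates of 200 CSR
localities, and the full pipeline at the reference scenario's ~1500
specimens / ~400 localities — sizes chosen so the whole suite completes in a
few minutes on one CPU while keeping Monte-Carlo error well inside the
asserted bounds. Geometric identities are asserted to 1e−9 relative area
(floating-point accumulation over hundreds of clipped parts), boundary
containment uses a 1e−9-of-scale snap tolerance, and the projection
round-trip is required to hold at 1e−6 degrees (≈ 0.1 m).

## Known limitations

* Convex hulls overestimate ranges with concave or disjunct distributions
  (no alpha shapes or kernel ranges by design), and underestimate the true
  extent of a region sampled at finitely many localities — visible in the
  worked example, where the recovered inside-fraction against *inferred*
  transitional ranges (0.78) sits below the generator's configured 0.9.
* Distance-band weights are binary; no kernel or row-standardised variants.
* The hot/cold cut at 2.5 sd is not multiplicity-adjusted by default, by
  fidelity to the source workflow; use `fdr = TRUE` for exploratory maps.
* O(n²) distance matrices cap practical problem sizes at a few tens of
  thousands of localities — ample for museum collections.
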