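# mimicmaps

Spatial characterisation of digitised natural-history collections, built
around the classic study system of polymorphic Batesian mimicry in the
African Mocker Swallowtail (*Papilio dardanus*). Museum voucher databases
record, per pinned specimen, a voucher id, sex, female wing-pattern morph,
subspecies, country and a geocoded collection locality with a positional
error in km. `mimicmaps` answers three questions such a database poses:

1. **Where was collecting effort concentrated?** Sampling density is never
   uniform; any distributional claim must be read against the collection's
   hot spots.
2. **Where does each taxon occur?** First-pass range polygons per subspecies
   or morph group, trimmed by the environment they actually occupy.
3. **Are focal phenotypes spatially associated with a region?** Here: are
   "imperfect" mimetic female forms concentrated in the transitional
   populations where the eastern and western lineages meet?

## Methods at a glance

* **Geocode filtering** keeps records with a positional error strictly below
  40 km, the accuracy cut used when the collection was gazetteer-geocoded.
* **Projection**: spherical Albers equal-area conic for Africa (central
  meridian 25°E, standard parallels 20°N / 23°S), so planar distances are
  metres and areas are preserved.
* **Scale selection**: global Moran's I of per-locality specimen counts
  x_i over binary distance-band weights w_ij,

      I = (n/W) Σ_ij w_ij z_i z_j / Σ_i z_i²,  z_i = x_i − x̄,  W = Σ_ij w_ij,

  z-scored against E[I] = −1/(n−1) with the randomisation variance, swept
  over increasing bands; the band with the highest z is the scale of
  strongest clustering.
* **Hot spots**: Getis–Ord Gi* at the chosen band (self-inclusive weights),

      Gi* = [Σ_j w_ij x_j − x̄ Σ_j w_ij] / (S √{[n Σ_j w_ij² − (Σ_j w_ij)²]/(n−1)}),

  with localities above 2.5 standard deviations labelled hot. A circle-count
  density surface (280 km radius) with 7 quantile classes is produced
  alongside as the heatmap layer.
* **Ranges**: convex hull of each taxon's localities, clipped to the
  environmental classes (20 km block-majority raster) in which the taxon has
  at least one occurrence.
* **Overlay**: boundary-inclusive point-in-polygon counts of imperfect-mimic
  specimens against the union of the transitional subspecies' range
  polygons.

A first-class synthetic-data generator (`reference_scenario()`,
`generate_records()`, `generate_raster()`, `generate_csr()`) emulates the
statistical structure of such a collection — clustered over-sampling,
regional morph compositions with a leaking transitional concentration of
imperfect forms, and a class-structured environmental raster — so the whole
pipeline is testable and calibrated without any external data.

## Worked example

```r
library(mimicmaps)

scen <- reference_scenario(seed = 42)   # the documented synthetic scenario
rs   <- generate_records(scen)
rs
#> Record set: 1518 specimen record(s)
#>   provenance: synthetic scenario (seed 42)
#>   geocoded: 1518 of 1518

geo <- filter_geocoded(rs, max_error_km = 40)   # strict < 40 km
nrow(geo)
#> [1] 997

head(tabulate_records(rs, "country"), 3)
#>        key count
#> 1 Tanzania   574
#> 2 Cameroon   523
#> 3   Uganda   376

hp <- hotspot_pipeline(geo, bands = reference_bands())
hp$band_m / 1000          # Moran-selected neighbourhood scale, km
#> [1] 200
hp$gi
#> Gi* hot-spot result: 352 locations, band = 200000 m, threshold = 2.5 sd
#>   hot: 206, cold: 0, none: 146

raster <- generate_raster(scen)
ranges <- infer_ranges(geo, raster, group_by = "subspecies")
ranges[["tibullus"]]
#> Range polygon for 'tibullus'
#>   hull: 10 vertices, area 2921069 km^2
#>   clipped: 162 part(s), area 2729243 km^2
#>   occupied classes: 1

ov <- overlay_imperfect(geo, poly = c(ranges[["meseres"]]$clipped,
                                      ranges[["polytrophus"]]$clipped))
ov
#> Overlay vs 'transitional': 45 imperfect specimen(s), 35 inside, 10 outside
#>   inside fraction: 0.778
```

Reading the output: the Moran sweep recovers the 200 km scale of the three
planted collection clusters; all of their localities, and essentially none
of the diffuse background, exceed the 2.5 sd Gi* cut. The tibullus hull
loses about 7% of its area to the unoccupied arid class. Of the geocoded
imperfect-mimic specimens, 78% fall inside the *inferred* transitional
ranges — an underestimate of the generator's configured 90%, because a
convex hull of finitely many localities is always a subset of the true
region it samples.

The same stages run as a file-based pipeline with a run manifest:

```r
cfg <- run_config(records = "records.csv", raster = "raster.asc",
                  outdir = "out", seed = 42)
run_pipeline("simulate", cfg)
run_pipeline("all", cfg)   # summarise, hotspots, ranges, overlay
```

or from a shell via the wrapper in `inst/cli/mimicmaps.R`.

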