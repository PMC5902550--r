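# fishweirs

Spatial and circular statistics for earthen fish-weir landscapes on
seasonally flooded savannahs.

Floodplain fisheries built from low earthen embankments — zigzag **weirs**
whose V-shaped indentations point downstream, rectilinear **causeways** and
**canals**, and excavated **ponds** rimmed by raised **berms** — leave a
distinctive archaeological signature. Whether such a landscape worked as an
integrated fish-trapping system is a statistical question: are ponds placed
near the earthworks more often than chance allows, do the V-structures and
berms align with the flood-flow direction, and how strongly does the system
concentrate fish from a large capture area into small collecting
structures? `fishweirs` implements that analysis end to end for landscape
archaeologists and spatial ecologists, together with a synthetic landscape
generator with known ground truth, so every estimator in the package can be
calibrated and its power measured.

## Methods at a glance

* **Monte Carlo association test.** With `n` pond centroids and a cutoff
  `d*` (default 35 m), the observed count `k_obs` of ponds within `d*` of
  the nearest linear/zigzag feature is compared against `N` random
  placements of `n` points uniform in the sub-basin polygons (or uniform by
  arc length *along* the weirs, for the pond-to-V-structure test). The
  p-value is the exceedance fraction
  `p = #{ sims with k >= k_obs } / N`, reported as the bound `< 1/N` when
  no simulation reaches `k_obs` (the add-one estimator `(x+1)/(N+1)` is
  stored alongside).
* **Undetected-pond sensitivity.** How many additional ponds — all assumed
  farther than `d*` from every feature — would have to have escaped
  detection before the association stops being significant? The total count
  grows in steps of 10 (100 simulations per step) with `k_obs` held fixed;
  the threshold is the first extra-pond count with `p > 0.05`.
* **Circular statistics.** Kuiper's rotation-invariant uniformity test
  `V_n = D+ + D-`, reported raw and standardized as
  `V_n (sqrt(n) + 0.155 + 0.24/sqrt(n))` with its asymptotic upper tail;
  the Watson-Williams F-test for equal mean directions with the
  `1 + 3/(8 kappa)` correction; circular means; berm woody-arc extents and
  their accumulation around the compass.
* **Morphometry.** V-structure median length, opening width and their
  ratio; Welch (or pooled) two-sample t computable from raw measurements
  *or* from published summary statistics.
* **Concentration factors.** The basin is partitioned into inter-weir
  capture areas by splitting the sub-basin polygon along each weir
  polyline; the concentration factor is capture-area surface divided by
  collecting-structure surface (pond areas plus pondless-V triangles, or
  `k * pi/4` m² for `k` trap fishways of 1 m diameter).

All coordinates are planar metres in a projected CRS; the package never
reprojects and refuses inputs whose bounding box looks like lon/lat
degrees. Data exchange is GeoJSON FeatureCollections plus attribute CSVs
(`save_landscape()` / `load_landscape()` round-trip coordinates exactly).

## Worked example

```r
library(fishweirs)

# a survey-scale synthetic landscape: 2 sub-basins, 3 zigzag weirs each,
# 150 ponds of which 60% are planted within 35 m of a V apex
sim <- generate_landscape(generator_config(seed = 11, n_ponds = 150))
ls <- sim$landscape
ls
#> <landscape> 2 sub-basin(s), 8 linear feature(s), 150 V-structure(s), 150 pond(s)
#>   CRS: synthetic planar metres

mc_association_test(ls, "features", cutoff = 35, n_sims = 1000, seed = 2)
#> <association_result> target = features
#>   108 / 150 ponds within 35 m; p < 0.001 (n_sims = 1000)

v_az <- sapply(ls$v_structures, function(v) v$orientation)
kuiper_uniformity(v_az)
#> Kuiper uniformity test: V = 0.7548, standardized = 9.38, n = 150, p < 1e-12 (asymptotic)

circular_mean(v_az)$mean   # generator flow azimuth was 30 degrees
#> [1] 27.41156

two_sample_t_from_summary(group_summary("Bolivia", 100, 30.0, 18.5),
                          group_summary("Zambia",  100, 5.3,  2.4))
#> Two-sample t (welch): Bolivia vs Zambia: t = 13.240, df = 102.3, p = 6.52226e-24
```

Reading the output: 108 of 150 ponds sit within the 35 m cutoff while none
of 1000 random placements reached that count, so the association p-value is
bounded above by 1/1000; the V orientations are far from uniform
(standardized Kuiper 9.38) and their circular mean recovers the generator's
flow azimuth to within ~2.6 degrees; and the published Bolivian and Zambian
V median-length summaries differ by a Welch t of 13.2, which prints as the
integer 13.

The whole pipeline (simulate → associate → sensitivity → orient → morpho →
concentrate → report) can be driven from a YAML config with
`run_pipeline()`, or from a shell via
`inst/scripts/fishweirs-pipeline.R`.

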