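---
title: "Methods: spatial and circular statistics for fish-weir landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial and circular statistics for fish-weir landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fishweirs` analyses the spatial organisation of earthen fishery landscapes:
zigzag weirs carrying V-shaped structures, causeways and canals, ponds with
berms, all digitized as vector features in one projected plane. This
vignette explains the models behind each analysis stage, the tunable
parameters and their defaults, the design choices made where the design was
genuinely open, and what the synthetic-data calibrations do and do not show
about real data.

## The data model

All coordinates are planar metres (easting/northing) in an unspecified
metric projection; the package never reprojects, because every quantity it
computes — distances, areas, azimuths — is projection-local at the scale of
a single floodplain (a few kilometres). `load_landscape()` refuses inputs
whose bounding box fits inside [-180, 180] x [-90, 90], the signature of
longitude/latitude degrees, unless the caller overrides the guard.

Azimuths are compass bearings: degrees clockwise from geographic north, in
[0, 360). Every trigonometric conversion goes through
`azimuth_to_unit()` / `azimuth_from_displacement()`, so the bearing and
mathematical-angle conventions can never be silently mixed.

A V-shaped structure is stored as three points — the apex and the two arm
endpoints, the arms treated as straight embankment segments. Its
orientation is the azimuth from the opening midpoint (the midpoint of the
arm endpoints) to the apex: the direction the point of the V faces, which
for a functioning weir is downstream. The stored orientation is validated
against the geometry to 1e-6 degrees whenever a landscape is assembled, so
serialized attributes can never drift from the coordinates.

Ponds are represented by their centroids for all distance computations;
their surface enters only through the `area` attribute. This mirrors how
such features are digitized from imagery: outlines are approximate
(vegetation-based), centroids and areas are robust.

## Monte Carlo association testing

The core inference asks whether ponds lie closer to anthropogenic features
than a random arrangement would put them. For the feature-level test the
statistic is the count of ponds whose nearest weir/causeway/canal lies
within a cutoff distance; the null distribution comes from redistributing
the same number of points uniformly over the sub-basin polygons (basins
chosen with probability proportional to area, then box-rejection sampling
inside the polygon). For the V-structure test, only the ponds already
associated with a weir are kept, and the null redistributes them uniformly
*by arc length along the weir polylines* — the appropriate reference
population for the question "given a pond on a weir, is it near a V?".

Choices worth stating explicitly:

* **Cutoff.** The 35 m default is a configuration value. In the field study
  this package reimplements, the cutoff was chosen by eye from a dip in the
  observed distance histogram; `distance_histogram()` supports that
  workflow but nothing auto-detects a cutoff.
* **Exceedance convention.** `p = #{k_sim >= k_obs}/N`, with *at least* the
  observed count. With zero exceedances the honest statement is a bound,
  `p < 1/N`, and that is what the result prints; the add-one estimator
  `(x+1)/(N+1)` is stored for users who need a proper p-value (it is also
  the reported `p_value` floor, so the stored number is never 0).
* **Pond-to-V distance** is measured to the V *apex* by default. The apex
  is the only geometrically unambiguous landmark on a V; measuring to the
  nearest point on the arms is available via `v_reference = "arms"`.
* **Ties.** A pond exactly equidistant from a weir and a causeway is
  attributed to the weir (ties are measure-zero events; the rule only
  matters for hand-built fixtures).
* **Pooling.** Observed counts are pooled across sub-basins, matching how
  such counts are reported for multi-basin surveys.
* **Null placement** is uniform over the full basin polygon. If parts of a
  basin were masked during digitization (e.g. forest inliers), the null is
  slightly conservative there; the package does not model masks.

The simulated points are plain points: footprint overlap and minimum
spacing between simulated ponds are ignored, consistent with representing
observed ponds by centroids.

### Sensitivity to undetected ponds

Ponds can be missed on imagery. `undetected_pond_sensitivity()` holds the
*observed* within-cutoff count fixed — any hypothetical missed pond is
assumed to lie beyond the cutoff from every feature, the worst case for the
association — and grows the total pond count in steps (default 10, with 100
simulations per step), recomputing the exceedance p-value at each step. The
threshold is the first number of extra ponds at which p exceeds alpha. At
100 simulations per step the p estimate near alpha = 0.05 has a standard
error of about 0.02, so the threshold carries Monte Carlo noise of a step
or two when the p-trace rises gently; `sims_per_step` is configurable for a
smoother trace.

## Circular statistics

**Kuiper's test** of circular uniformity uses `V_n = D+ + D-`, the sum of
the maximal positive and negative deviations of the empirical CDF from the
uniform CDF, computed by the standard order-statistic formula; it is
invariant to rotating the origin and to reflection. Two statistics are
reported: the raw `V_n` (bounded by 2) and the standardized
`V_n (sqrt(n) + 0.155 + 0.24/sqrt(n))`, whose asymptotic upper tail
`Q(lambda) = 2 * sum_{j>=1} (4 j^2 lambda^2 - 1) exp(-2 j^2 lambda^2)`
gives the p-value. Published orientation analyses print statistics in the
6-9 range for n of 70-150, which is only possible on the standardized
scale, so that is the scale this package prints; the raw statistic is kept
alongside because the standardization is a convention, not part of the
data. Asymptotic probabilities below 1e-12 are floored and labelled
`"< 1e-12"` — beyond that point the tail series is numerically meaningless
and chasing printed bounds like 1e-36 would be false precision. For n < 5
(or on request) the p-value is computed by Monte Carlo resampling from the
uniform circle instead.

**The Watson-Williams test** compares the mean directions of two samples
under a shared von Mises concentration. The F statistic
`((N-2)(R1+R2-R)) / (N-R1-R2)` is multiplied by the standard correction
`1 + 3/(8 kappa_hat)`, with `kappa_hat` the inverse-A estimate from the
within-sample mean resultant length `(R1+R2)/N`. The correction is always
applied; when `kappa_hat` falls outside [1, 10] — too dispersed for the
test's assumptions, or so concentrated the correction is negligible — a
warning string is attached to the result rather than silently changing the
computation.

**Berm arcs.** A berm is detected as an arc of woody vegetation on the pond
rim, recorded by its extreme azimuths running clockwise. `arc_extent()` is
the clockwise span; a degenerate start == end arc has extent 0 unless
flagged full-circle (360). `cumulate_arcs()` counts, for each 1-degree bin,
the arcs covering the bin midpoint; total occupancy equals the summed
extents divided by the resolution, up to rounding at arc edges.

Berm "orientation" is the azimuth from the pond centre to the rim point
with the highest soil level, the quantity the berm high-point attribute
stores.

## Morphometry

`v_dimensions()` returns the median length (apex to opening midpoint),
opening width (distance between arm endpoints) and their ratio. "Width" is
the straight distance between the arm *endpoints*; if arms curve, the
maximum distance anywhere along the arms could differ, but with arms stored
as straight segments the two coincide.

`two_sample_t_from_summary()` computes Welch's t directly from group means,
standard deviations and sizes — the form needed to re-derive published
comparisons from printed summaries — with Welch-Satterthwaite degrees of
freedom; the pooled-variance variant is available, and for equal group
sizes the two t statistics coincide exactly (only the df differ). Welch is
the default because equal variances are not defensible for measurements
spanning an order of magnitude between systems. Published integer t values
are matched by rounding the absolute statistic to the nearest integer.

## Concentration factors

`partition_interweir_areas()` splits a sub-basin polygon along each weir
polyline (the weir must cross the basin boundary exactly twice). The split
is exact polygon surgery — boundary crossings are located on both the
polyline and the ring, and the two pieces share the polyline's interior
vertices — so zigzag weirs partition the basin with machine-precision area
conservation, which the tests assert at 1e-6 relative.

Pieces are ordered along the basin's flow direction (the circular midpoint
of the flow interval); each piece except the most downstream is bounded
downstream by a weir. Collecting structures of a piece are its ponds plus
the downstream weir's "pondless" Vs — Vs with no pond within the cutoff of
their apex. A pondless V contributes the area of the triangle spanned by
its apex and arm endpoints: no convention exists for the surface to assign
a V without a mapped pond, and the triangle is the minimal geometric
reading of the structure's footprint. In trap-based mode each fishway-gap V
contributes a circular interception area of 1 m diameter (`pi/4` m²). The
concentration factor is capture-area surface over collecting surface; it is
invariant under coordinate scaling by construction, and trap-mode factors
exceed pond-mode factors whenever pond areas dwarf trap circles.

Users reproducing a manual workflow can supply hand-digitized inter-weir
polygons as `interweir_area` objects instead of using the partition helper.

## The synthetic landscape generator

No GIS dataset accompanies the field study this package reimplements, so
the generator is the package's test bed: it builds landscapes with the
statistical structure the analyses assume, with every latent draw recorded
as ground truth. The defaults are the study conditions:

* two rectangular sub-basins, 1500 x 1200 m, sharing one flow azimuth
  (default 30 degrees, +/- 15 degrees interval);
* three zigzag weirs per basin crossing perpendicular to flow, V apexes
  displaced downstream with von Mises orientation noise (kappa = 8);
* 382 ponds in total, 60% placed 2-33 m upstream of randomly chosen V
  apexes and the rest uniform in the basins — the survey-scale counts and
  association strength reported for the mapped landscape;
* pond areas lognormal with moments matched analytically to mean 525 m²
  and s.d. 548 m²: with s.d. exceeding the mean, a symmetric law is
  impossible and the lognormal is the standard positive right-skewed
  choice;
* berm high azimuths von Mises about the flow azimuth (kappa = 8), woody
  arcs truncated normal (mean 60, s.d. 30 degrees), and a
  present/undetermined/absent detectability mix of 0.58/0.36/0.06,
  reflecting that roughly a third of surveyed ponds could not be scored
  from imagery.

The basin size is a desk-scale choice (the real site covers ~155 km²; the
analyses are scale-free, and tests must run in minutes), stated here as the
package's own problem size. Geometry and attribute draws use separate
seed substreams (`substream_seed()`), so changing the pond count never
reshuffles the weirs.

`generate_bolivia_like()` / `generate_zambia_like()` draw V dimension
samples for the two fishery systems. Length and width are a *correlated
bivariate lognormal* whose log-moments are matched to the published mean
and s.d. of length and width, with the log-scale correlation set from the
published ratio s.d. (for the Bolivian system the implied correlation is
about 0.79, for the Zambian about 0.06). Independent draws — or truncated
normals, with the Bolivian width's coefficient of variation near 0.9
putting mass at the truncation floor — produce ratio distributions
nowhere near the published ones. Matching length, width *and* ratio
moments exactly is overdetermined: with length and width matched, the
implied ratio means are 0.99 (published 0.98) and 1.65 (published 1.60).
The Zambian variant marks every apex with a fishway gap (width 1.0 +/- 0.3
m, truncated at 0.1 m) and carries no ponds.

**What the generator does not emulate:** irregular basin outlines, spatial
inhomogeneity of pond density, curved or branching weirs, measurement error
in digitized coordinates, and any correlation between pond area and
placement. Calibration results on generated landscapes therefore
demonstrate that the estimators are correct and well-sized *under the
stated model*, not that a particular field dataset would yield any
particular value.

## Numerical choices

* Uniform points in a polygon use bounding-box rejection sampling (basins
  are near-convex, so acceptance is high); the iteration count is capped
  and pathological thin polygons fail loudly rather than spin.
* Polyline sampling picks a segment with probability proportional to its
  length, then a uniform offset — exactly uniform by arc length.
* Point-to-segment-set distances and point-in-polygon tests are C++
  (Rcpp): the calibration suites evaluate ~10^8 point-segment pairs.
  Boundary points count as inside; containment is even-odd.
* GeoJSON numbers are written with 17 significant digits, so
  `load_landscape(save_landscape(x))` reproduces coordinates bit-for-bit.
* Monte Carlo p-values use the exceedance (>=) convention throughout,
  making them conservative (stochastically at least uniform under the
  null).
* The von Mises sampler is the Best-Fisher rejection algorithm; kappa = 0
  degenerates to the uniform circle.

## Problem sizes used by the test suite

The calibration tests run 500 null landscapes (100 ponds, 1000 simulations
each) for the association test's size, 40 survey-scale landscapes for its
power, 2000 replicates for Kuiper size at n = 71, 1000 replicates for
Watson-Williams size at n = 100 + 100, and a 10,000-simulation analytic
cross-check; the full suite completes in roughly ten minutes on one CPU.
These sizes bound the Monte Carlo noise well inside the asserted bands
(e.g. a true 5% rate at 500 replicates has a 99% interval of roughly
[0.03, 0.08]).

## Known limitations

* The partition helper requires each weir to span its basin with exactly
  two boundary crossings; weirs ending inside the basin need hand-digitized
  capture areas.
* The asymptotic Kuiper tail is accurate for n >= 5 but cannot resolve
  probabilities below 1e-12; extreme uniformity violations are reported as
  bounds.
* The Watson-Williams test assumes a common concentration; strongly
  unequal concentrations are not detected, only flagged indirectly through
  the pooled kappa warning.
* Sub-basin polygons must be simple; the self-intersection check is
  O(n²) in the vertex count, adequate for digitized outlines but not for
  very high-resolution rings.
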