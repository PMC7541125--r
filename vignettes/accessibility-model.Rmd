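---
title: "Modelling volunteer coverage and walking access to health facilities"
author: "chwaccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling volunteer coverage and walking access to health facilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chwaccess)
```

## The problem

Rural community health programs in Madagascar deploy volunteer health
workers (ACs, *agents communautaires*) at the level of the fokontany, the
lowest administrative unit. Each AC is supervised by a primary health
center (CSB) and restocks at a supply point (PA), and reaches both on
foot. Two questions drive the analysis this package implements:

1. **Coverage** — how many people, and how much terrain, is each volunteer
   responsible for, and how do fokontany compare against policy thresholds
   of 1,000 people and 25 km² per AC?
2. **Access** — how long is the one-way walk from a fokontany to its
   assigned CSB and PA, how much shorter would the walk to the *closest*
   facility be, and how many fokontany sit more than 2 or 4 hours out?

Both questions are answered on a raster model of the landscape: every
100 m × 100 m cell carries population, land cover, elevation and a
derived *friction* value — the minutes needed to traverse that cell on
foot.

## The cost-distance model

### Walking speed

The baseline is 5 km/h on bare ground and on all roads. Other land-cover
classes reduce it; the shipped defaults are

| class        | speed (km/h) |
|--------------|--------------|
| bare / road  | 5.0          |
| cropland     | 4.0          |
| shrub        | 3.5          |
| dense forest | 2.5          |
| open water   | impassable   |

These class speeds, like the river-crossing delays below, are
**configuration, not measured constants**: they are plausible for rural
foot travel and are exposed in `speed_table()` (with YAML read/write) so a
study can substitute field-validated values.

### Slope

Slope enters through Tobler's hiking function,
$W(s) = 6\,e^{-3.5\,|s + 0.05|}$ km/h with $s$ the rise-over-run. We
apply it as a multiplicative factor normalized to flat ground,
$W(s)/W(0)$, so the configured 5 km/h baseline is preserved exactly on
the flat rather than being overwritten by Tobler's own 5.04 km/h flat
speed — this avoids double-counting the baseline. The factor peaks at
$e^{0.175} \approx 1.19$ on a gentle 5% downhill and is symmetric about
$s = -0.05$. Because the accumulated-cost surface is isotropic, the
uphill/downhill distinction is deliberately collapsed to a slope
magnitude (computed with a Horn-style 3×3 kernel, one-sided at borders):
this matches the cost-distance tool family used for this kind of
accessibility analysis. `apply_slope_to_roads` defaults to `TRUE`
because the road network in such areas is mostly unpaved paths.

### Rivers

The river network is derived from the elevation model itself: D8 flow
routing (each cell drains to its steepest-descent neighbour, with
drop-over-distance weighting so a cardinal neighbour beats a diagonal one
on equal drop), flow accumulation, and Strahler stream ordering. Stream
cells are those with at least `stream_threshold` upslope cells (default
50, i.e. 0.5 km² at 100 m resolution). Strahler order stands in for
width: by default orders ≤ 3 are small streams (fordable, no delay),
orders 4–5 are medium rivers (20–60 m, dugout-canoe crossing, default
delay 15 min) and orders ≥ 6 are large rivers (over 60 m, ferry, default
60 min). Both the accumulation threshold and the order→width map are
configuration knobs: the width classes and the existence of canoe/ferry
delays are the anchored part of the model, their calibration is not.
Open water *off* the mapped river network is impassable; water cells *on*
the network are traversable at the baseline speed with the crossing delay
added once per cell.

Depressions in the DEM are filled by priority-flood with an epsilon
gradient (default $10^{-4}$ m per cell step) before any routing, so the
flow field has no pits and no unresolved flats; ties in the D8 descent
choice break in the fixed neighbour order N, NE, E, SE, S, SW, W, NW.
These tie rules exist purely for bit-reproducibility.

### Accumulated cost

Travel time from a facility is exact multi-source Dijkstra on the
8-connected grid, with the move cost between adjacent cells $i \to j$
defined as $\tfrac12 (f_i + f_j)\, d$, $d = 1$ for cardinal and
$\sqrt 2$ for diagonal moves — the convention of the standard
accumulated-cost-surface tools, which makes results reproducible against
them. Source cells start at 0 minutes; starting at half the source-cell
traversal would be equally defensible, and 0 is chosen and documented as
a convention. Facilities snap to the cell containing their coordinates,
or to the nearest passable cell within 3 cells (an error beyond that).

### Fokontany summaries

An AC's location within its fokontany is unknown, so every *habitable*
cell — population density at least 10 persons/km² — is treated as an
equally likely AC location, and the fokontany's travel time is the
unweighted mean of the field over its habitable cells. On the synthetic
data the 10 persons/km² threshold retains well over 90% of the
population, mirroring the conservative choice made with gridded
population products. A fokontany with no habitable cell falls back to
all of its cells and is flagged.

Travel times are one-way, dry-season, walking-only. Rainy-season
friction, mechanized transport and anisotropic costs are out of scope.

## Coverage analysis

Fokontany population is the zonal sum of the population raster over the
fokontany polygon (cell centers inside the ring); area is the planar
shoelace area in the meter-unit analysis CRS. Population and area are
split **evenly** across the fokontany's ACs — the stated assumption of
the deployment analysis; heterogeneous intra-fokontany splits are out of
scope. Threshold classification is inclusive (≤ 1,000 people, ≤ 25 km²),
matching the "or fewer / or less" reading, and fokontany with no ACs are
flagged rather than classified. Travel-time bins are likewise inclusive
at the top: 120 min falls in "within 2 hours".

## Reassignment scenarios

"Closest" is defined at the fokontany level: the eligible facility
minimizing the fokontany-mean travel time, because reassignment moves a
fokontany's ACs as a unit. (A per-cell multi-source minimum is the other
defensible reading; the fokontany-level argmin is the implemented
default, and the travel-time matrix returned by `travel_time_matrix()`
lets a user compute either.) Facilities supporting no ACs are not
eligible reassignment targets. Fokontany whose commune has no PA are
excluded from PA scenarios with an explicit reason, and exclusion counts
are part of the report. By construction the closest-facility time can
never exceed the assigned-facility time for a non-excluded fokontany, so
reassignment can only improve means, medians and the share beyond 4
hours — the package tests assert exactly this direction.

## The synthetic landscape

No real rosters or rasters ship with the package; a seeded generator
(`landscape_spec()`, `simulate_landscape()`) produces a self-consistent
study area so the full pipeline is testable:

- **Terrain**: a north-high planar trend (150 m drop) plus a correlated
  Gaussian field (amplitude 300 m, correlation length 15 cells),
  depression-filled. Zero roughness degenerates to the plane.
- **Land cover**: a second correlated field cut at mixture-weight
  quantiles (15% bare, 35% cropland, 30% shrub, 20% forest; no open
  water by default so the extent stays fully traversable).
- **Settlements**: 30 cores sampled with valley-bottom bias and minimum
  separation; population is a sum of Gaussian kernels (peak 1,200
  persons/km², sd 400 m, lognormal size factors), giving fokontany
  populations of a few hundred to a few thousand — the range typical of
  these districts.
- **Administrative units**: fokontany are Voronoi cells of the cores;
  communes are k-means clusters of cores; districts a west/east split.
- **Roads**: the Euclidean minimum spanning tree of the cores, the
  simplest connected network that exercises road overrides.
- **Facilities and roster**: 20% of settlements host a CSB; PAs are
  spread one per commune until the PA budget (17% of settlements) is
  exhausted, so a minority of communes — and their fokontany — end up
  without a PA. One CSB is given no volunteers to exercise the
  eligibility rule. AC counts are drawn from a distribution concentrated
  on 2 (92%, range 1–6). Assignment uses travel-time closeness, with
  misassignment probabilities 0.31 (CSB) and 0.25 (PA) — the observed
  shares of fokontany not assigned to their closest facility in the
  deployment this emulates.

What the generator does **not** emulate: real road-network topology and
quality, seasonal hydrology, intra-fokontany population structure beyond
single kernels, and facility siting politics. Passing tests therefore
demonstrate the correctness and internal consistency of the *method* —
oracle equivalence of the spatial algorithms, conservation laws,
monotonicity and boundary semantics — not the reproduction of any
real-world travel-time figure.

```{r example, eval = FALSE}
spec <- landscape_spec(seed = 7)
land <- simulate_landscape(spec)
res <- analyse_landscape(land)
res$coverage_summary[c("prop_below_pop", "prop_below_area", "prop_below_both")]
res$bins$csb_assigned
```

## Numerical choices and problem sizes

- Grid algorithms (depression filling, cost distance) are compiled;
  everything else is vectorized R. A full 200×200 run (simulate through
  report) takes a couple of seconds.
- Tests compare the grid Dijkstra against an independent explicit-graph
  shortest path (igraph) on 100 random 20×20 instances exactly, and flow
  accumulation against a brute-force path walk on random ≤15×15 DEMs.
  Property tests that loop over many landscapes use a reduced 90×90,
  12-settlement spec, since the properties checked (reassignment
  direction, exclusion bookkeeping, determinism) do not depend on extent;
  the end-to-end determinism check runs the full 200×200 default twice
  and compares outputs byte for byte.
- All randomness flows from the single spec seed through fixed per-stage
  offsets, so any layer can be regenerated in isolation.

## Known limitations

- Isotropic cost: uphill and downhill legs of the same path cost the
  same, which understates asymmetric round trips.
- The Strahler→width calibration and crossing delays are defaults, not
  data; studies with river measurements should override them.
- Fokontany means treat habitable cells as equally likely AC homes;
  population-weighted means are deliberately not used (the equal-
  probability contract), which can differ where settlement is very
  uneven.
- Polygon zonal statistics use cell centers; slivers narrower than a
  cell may capture no cells and trigger the all-cells fallback.
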