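# chwaccess

Geographic accessibility modelling for community health volunteer
deployment.

Rural health programs in Madagascar field volunteer community health
workers (*agents communautaires*, ACs) in each fokontany — the lowest
administrative unit — supervised by primary health centers (CSB) and
resupplied at supply points (PA), all reached on foot. This package
implements the GIS model behind two deployment questions:

- **Coverage**: population and surface area per volunteer, with each
  fokontany classified against inclusive thresholds of ≤ 1,000 people
  and ≤ 25 km² per AC (population and area split evenly among a
  fokontany's ACs).
- **Access**: one-way pedestrian travel time from each fokontany to its
  *assigned* and to its *closest* CSB and PA, and the effect of
  reassigning volunteers to the closest facility.

## The model

Travel time is computed on a friction raster: each 100 m cell costs

```
minutes = (cell_size / 1000) / v(cell) * 60        (+ crossing delay on rivers)
v(cell) = v_class or v_road, scaled by W(s)/W(0)
W(s)    = 6 exp(-3.5 |s + 0.05|)   (Tobler's hiking function, s = slope)
```

with a 5 km/h baseline on bare ground and roads and reduced class speeds
elsewhere (configurable via `speed_table()`). Rivers come from the DEM
itself — D8 flow routing, flow accumulation, Strahler stream order — and
medium (canoe) and large (ferry) rivers add fixed crossing delays.
Accumulated cost from each facility is exact multi-source Dijkstra on
the 8-connected grid with move cost `0.5 (f_i + f_j) d`,
`d ∈ {1, √2}`. A fokontany's travel time is the unweighted mean over its
*habitable* cells (density ≥ 10 persons/km²), each treated as an equally
likely volunteer location.

Because the real rosters and rasters are not redistributable, the
package includes a seeded synthetic-landscape generator (terrain with
drainage, clustered settlements, MST roads, Voronoi fokontany grouped
into communes and districts, facilities, an AC roster concentrated on 2
volunteers per fokontany) that exercises every stage of the pipeline.
See the vignette in `vignettes/accessibility-model.Rmd` for the full
model description and its assumptions.

## Worked example

```r
library(chwaccess)
spec <- landscape_spec(seed = 7)        # 20 x 20 km, 100 m cells, 30 fokontany
land <- simulate_landscape(spec)
res  <- analyse_landscape(land)
```

Or as a workflow (each step also reads/writes the on-disk formats:
ESRI ASCII rasters, GeoJSON vectors, CSV tables):

```sh
Rscript analysis/01_simulate.R --seed 7     # writes results/landscape/
Rscript analysis/02_coverage.R
Rscript analysis/03_travel_time.R
Rscript analysis/04_scenarios.R
```

which prints, for seed 7:

```
Population <= 1,000 per AC: 70%
Area <= 25 km2 per AC:      93%
Both thresholds met:        67%
...
CSB scenario (30 fokontany, 0 excluded):
  assigned: <=2h 70% | 2-4h 20% | >4h 10% | mean 1.71 h
  closest:  <=2h 93% | 2-4h 7% | >4h 0% | mean 0.93 h
  misassigned: 37%
```

Reading: 70% of fokontany keep each volunteer at or under 1,000 people;
walking one-way to the currently assigned health center averages 1.71 h
and exceeds 4 h for 10% of fokontany, while reassignment to the closest
eligible center (37% of fokontany are not assigned their closest) would
cut the mean to 0.93 h and empty the worst bin — reassignment can never
worsen a fokontany's time, only improve it. Fokontany in communes
without a supply point are excluded from PA scenarios and reported as
such.

## Layout

- `R/`, `src/` — package code (grid container and I/O, vector layers,
  synthetic generator, friction, hydrology, travel time, coverage,
  scenarios); compiled kernels for depression filling and cost distance.
- `analysis/` — the numbered workflow scripts shown above.
- `scripts/acceptance.R` — headline-quantity reproduction.
- `tests/testthat/` — unit, property and end-to-end tests.
- `vignettes/accessibility-model.Rmd` — methods and design rationale.
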