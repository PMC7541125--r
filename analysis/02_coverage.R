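#!/usr/bin/env Rscript
# Step 2: per-volunteer coverage. Reads the written input stack back from
# disk (population raster, fokontany polygons, roster) and classifies each
# fokontany against the 1,000-person and 25-km2 per-AC thresholds.

suppressPackageStartupMessages({
  library(optparse)
  library(chwaccess)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--in", type = "character", default = "results/landscape",
              dest = "indir"),
  make_option("--out", type = "character", default = "results")
)))

population <- read_grid(file.path(opts$indir, "population.asc"),
                        expected_cell_size = 100)
fokontany <- read_geojson(file.path(opts$indir, "fokontany.geojson"))
roster <- read.csv(file.path(opts$indir, "roster.csv"),
                   stringsAsFactors = FALSE)

pop <- zonal_population(population, fokontany)
areas <- layer_areas_km2(fokontany)
names(areas) <- fokontany$attrs$fokontany_id
cov <- coverage_table(pop, areas, roster)
s <- coverage_summary(cov)

dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
write.csv(cov, file.path(opts$out, "coverage.csv"), row.names = FALSE)

cat(sprintf("Fokontany analysed: %d; residual population outside polygons: %.1f\n",
            s$n, attr(pop, "residual")))
cat(sprintf("Population <= 1,000 per AC: %.0f%%\n", 100 * s$prop_below_pop))
cat(sprintf("Area <= 25 km2 per AC:      %.0f%%\n", 100 * s$prop_below_area))
cat(sprintf("Both thresholds met:        %.0f%%\n", 100 * s$prop_below_both))
cat("Per-AC population histogram:\n"); print(s$pop_hist)
cat("Per-AC area histogram (km2):\n"); print(s$area_hist)
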