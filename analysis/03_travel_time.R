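#!/usr/bin/env Rscript
# Step 3: one-way pedestrian travel times. Reads the friction raster,
# facility table, fokontany polygons and population back from disk, runs
# the least-cost accumulation from every facility, and averages over
# habitable cells per fokontany.

suppressPackageStartupMessages({
  library(optparse)
  library(chwaccess)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--in", type = "character", default = "results/landscape",
              dest = "indir"),
  make_option("--out", type = "character", default = "results")
)))

friction <- read_grid(file.path(opts$indir, "friction.asc"),
                      expected_cell_size = 100)
population <- read_grid(file.path(opts$indir, "population.asc"),
                        expected_cell_size = 100)
fokontany <- read_geojson(file.path(opts$indir, "fokontany.geojson"))
facilities <- read.csv(file.path(opts$indir, "facilities.csv"),
                       stringsAsFactors = FALSE)

mask <- habitable_mask(population)
fields <- facility_fields(friction, facilities)
for (kind in c("CSB", "PA")) {
  ids <- facilities$facility_id[facilities$kind == kind]
  tt <- travel_time_matrix(fields[ids], mask, fokontany)
  write.csv(data.frame(fokontany_id = rownames(tt), round(tt, 2),
                       check.names = FALSE),
            file.path(opts$out, sprintf("travel_time_%s.csv", tolower(kind))),
            row.names = FALSE)
  cat(sprintf("%s travel times (minutes): per-fokontany closest ranges %.0f-%.0f, grand mean %.0f\n",
              kind, min(apply(tt, 1, min)), max(apply(tt, 1, min)),
              mean(tt)))
}
cat("Travel-time matrices written to", opts$out, "\n")
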