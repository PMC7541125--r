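#!/usr/bin/env Rscript
# Step 4: assigned-versus-closest reassignment scenarios, accessibility
# bins and district summaries. Consumes the travel-time matrices written
# by step 3 plus the roster, and writes the report tables.

suppressPackageStartupMessages({
  library(optparse)
  library(chwaccess)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--in", type = "character", default = "results/landscape",
              dest = "indir"),
  make_option("--out", type = "character", default = "results")
)))

roster <- read.csv(file.path(opts$indir, "roster.csv"),
                   stringsAsFactors = FALSE)
read_tt <- function(kind) {
  df <- read.csv(file.path(opts$out, sprintf("travel_time_%s.csv", kind)),
                 check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$fokontany_id
  m
}
district <- setNames(roster$district_id, roster$fokontany_id)

for (kind in c("csb", "pa")) {
  tt <- read_tt(kind)
  sc <- scenario_table(roster, tt, toupper(kind))
  write.csv(sc, file.path(opts$out, sprintf("scenario_%s.csv", kind)),
            row.names = FALSE)
  ds <- district_summary(sc, district)
  write.csv(ds, file.path(opts$out, sprintf("district_summary_%s.csv", kind)),
            row.names = FALSE)
  ok <- !sc$excluded
  ba <- bin_travel_times(sc$assigned_minutes)
  bc <- bin_travel_times(sc$closest_minutes)
  cat(sprintf("\n%s scenario (%d fokontany, %d excluded):\n", toupper(kind),
              sum(ok), sum(sc$excluded)))
  cat(sprintf("  assigned: <=2h %.0f%% | 2-4h %.0f%% | >4h %.0f%% | mean %.2f h\n",
              100 * ba[1], 100 * ba[2], 100 * ba[3],
              mean(sc$assigned_minutes[ok]) / 60))
  cat(sprintf("  closest:  <=2h %.0f%% | 2-4h %.0f%% | >4h %.0f%% | mean %.2f h\n",
              100 * bc[1], 100 * bc[2], 100 * bc[3],
              mean(sc$closest_minutes[ok]) / 60))
  cat(sprintf("  misassigned: %.0f%%\n", 100 * mean(sc$misassigned[ok])))
  print(ds, row.names = FALSE)
}
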