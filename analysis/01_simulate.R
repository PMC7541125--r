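#!/usr/bin/env Rscript
# Step 1: generate the synthetic study area and write the full input stack
# (rasters, vector layers, roster) under results/landscape/.
#
# The default spec is a 20 x 20 km area at 100 m resolution with 30
# settlements, two districts and ~2 volunteers per fokontany; change the
# seed with --seed.

suppressPackageStartupMessages({
  library(optparse)
  library(chwaccess)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 7L),
  make_option("--out", type = "character", default = "results/landscape")
)))

spec <- landscape_spec(seed = opts$seed)
land <- simulate_landscape(spec)
write_landscape(land, opts$out)

cat("Simulated study area:\n")
print(land)
cat(sprintf("  habitable cells (>=10 persons/km2): %d (%.1f%% of population)\n",
            sum(land$mask$values > 0),
            100 * sum(land$population$values[land$mask$values > 0]) /
              sum(land$population$values)))
cat(sprintf("  river cells: %d (max Strahler order %d)\n",
            sum(land$rivers$strahler$values > 0),
            max(land$rivers$strahler$values)))
cat(sprintf("  fokontany with 2 ACs: %.0f%%\n",
            100 * mean(land$roster$n_acs == 2)))
cat("Input stack written to", opts$out, "\n")
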