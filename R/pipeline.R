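#' Run the full deployment analysis on a landscape
#'
#' Computes the two analyses on a simulated (or otherwise assembled)
#' landscape: the per-volunteer coverage table with threshold
#' classification, and the assigned-versus-closest travel-time scenarios
#' for health centers and supply points, with district summaries and
#' accessibility bins.
#'
#' @param land a `chw_landscape` from [simulate_landscape()].
#' @param pop_threshold,area_threshold_km2 coverage thresholds (defaults
#'   1000 persons, 25 km^2 per AC).
#' @return list: `coverage` (records), `coverage_summary`, `scenario_csb`,
#'   `scenario_pa`, `bins` (assigned/closest proportions per kind),
#'   `district_summary` (CSB and PA tables), `exclusions`.
#' @export
analyse_landscape <- function(land, pop_threshold = 1000,
                              area_threshold_km2 = 25) {
  stopifnot(inherits(land, "chw_landscape"))
  pop <- zonal_population(land$population, land$fokontany, land$zones)
  areas <- layer_areas_km2(land$fokontany)
  names(areas) <- land$fokontany$attrs$fokontany_id
  cov <- coverage_table(pop, areas, land$roster,
                        pop_threshold, area_threshold_km2)
  cov_sum <- coverage_summary(cov)

  sc_csb <- scenario_table(land$roster, land$tt_csb, "CSB")
  sc_pa <- scenario_table(land$roster, land$tt_pa, "PA")
  district <- stats::setNames(land$roster$district_id, land$roster$fokontany_id)

  bins <- list(
    csb_assigned = bin_travel_times(sc_csb$assigned_minutes),
    csb_closest = bin_travel_times(sc_csb$closest_minutes),
    pa_assigned = bin_travel_times(sc_pa$assigned_minutes),
    pa_closest = bin_travel_times(sc_pa$closest_minutes)
  )
  list(
    coverage = cov,
    coverage_summary = cov_sum,
    scenario_csb = sc_csb,
    scenario_pa = sc_pa,
    bins = bins,
    district_summary = list(csb = district_summary(sc_csb, district),
                            pa = district_summary(sc_pa, district)),
    exclusions = sc_pa[sc_pa$excluded,
                       c("fokontany_id", "facility_kind", "exclusion_reason")]
  )
}

format_report <- function(res) {
  pct <- function(x) sprintf("%d%%", round(100 * x))
  cs <- res$coverage_summary
  lines <- c(
    "Community health volunteer deployment report",
    "============================================",
    "",
    sprintf("Fokontany analysed: %d (plus %d without volunteers)",
            cs$n, sum(res$coverage$no_acs)),
    "",
    "Coverage per volunteer (even split within fokontany)",
    sprintf("  population <= 1,000 per AC: %s", pct(cs$prop_below_pop)),
    sprintf("  area <= 25 km2 per AC:      %s", pct(cs$prop_below_area)),
    sprintf("  both thresholds met:        %s", pct(cs$prop_below_both)),
    "",
    "One-way walking time, assigned vs closest facility")
  add_bins <- function(tag, a, b) {
    c(sprintf("  %s assigned: <=2h %s | 2-4h %s | >4h %s", tag,
              pct(a[1]), pct(a[2]), pct(a[3])),
      sprintf("  %s closest:  <=2h %s | 2-4h %s | >4h %s", tag,
              pct(b[1]), pct(b[2]), pct(b[3])))
  }
  lines <- c(lines,
             add_bins("CSB", res$bins$csb_assigned, res$bins$csb_closest),
             add_bins("PA ", res$bins$pa_assigned, res$bins$pa_closest),
             "",
             sprintf("Misassigned fokontany: CSB %s, PA %s",
                     pct(mean(res$scenario_csb$misassigned[!res$scenario_csb$excluded])),
                     pct(mean(res$scenario_pa$misassigned[!res$scenario_pa$excluded]))),
             sprintf("Excluded from PA scenario (no PA in commune): %d",
                     nrow(res$exclusions)))
  lines
}

#' Simulate, analyse and write all outputs
#'
#' The one-call pipeline: generates the landscape for `spec`, runs
#' [analyse_landscape()], and writes the input stack plus the result
#' tables (coverage, scenarios, district summaries, text report) to
#' `out_dir`. Output is fully determined by `spec` — rerunning with the
#' same spec reproduces every file byte for byte.
#'
#' @param spec a [landscape_spec()].
#' @param out_dir output directory.
#' @param table walking-speed table.
#' @return the analysis result list, invisibly.
#' @export
run_pipeline <- function(spec, out_dir, table = speed_table()) {
  land <- simulate_landscape(spec, table)
  res <- analyse_landscape(land)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_landscape(land, out_dir)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(res$coverage, "coverage.csv")
  wcsv(res$scenario_csb, "scenario_csb.csv")
  wcsv(res$scenario_pa, "scenario_pa.csv")
  wcsv(res$district_summary$csb, "district_summary_csb.csv")
  wcsv(res$district_summary$pa, "district_summary_pa.csv")
  writeLines(format_report(res), file.path(out_dir, "report.txt"))
  invisible(res)
}
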