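#' Zonal population totals
#'
#' Sums population cell values over each polygon (cell centers inside the
#' polygon), the standard way fokontany populations are aggregated from a
#' gridded population product. Population in cells outside every polygon
#' is reported as the `residual` attribute.
#'
#' @param population population grid (persons per cell).
#' @param polygons polygon layer with `fokontany_id` attribute.
#' @param zones optional precomputed [zone_raster()].
#' @return named numeric vector of persons per fokontany, with attribute
#'   `residual` (persons outside all polygons).
#' @export
zonal_population <- function(population, polygons, zones = NULL) {
  stopifnot(is_grid(population), is_vector_layer(polygons))
  if (is.null(zones)) zones <- zone_raster(polygons, population)
  v <- population$values
  v[is.na(v)] <- 0
  sums <- vapply(seq_along(polygons$geoms),
                 function(k) sum(v[which(zones == k)]), numeric(1))
  names(sums) <- polygons$attrs$fokontany_id
  attr(sums, "residual") <- sum(v[is.na(zones)])
  sums
}

#' Per-volunteer coverage table
#'
#' The first analysis of the deployment: population and surface area are
#' split evenly among a fokontany's volunteers (ACs), and each fokontany
#' is classified against inclusive policy thresholds — at most
#' `pop_threshold` people per AC and at most `area_threshold_km2` km^2 per
#' AC ("1,000 people or fewer", "25 km^2 or less").
#'
#' @param pop named vector of fokontany populations (persons), as from
#'   [zonal_population()].
#' @param areas named vector of fokontany areas in km^2.
#' @param roster data.frame with `fokontany_id`, `n_acs`.
#' @param pop_threshold persons per AC (default 1000).
#' @param area_threshold_km2 km^2 per AC (default 25).
#' @return data.frame of coverage records; fokontany with `n_acs == 0`
#'   get `NA` ratios and `no_acs = TRUE`.
#' @export
coverage_table <- function(pop, areas, roster,
                           pop_threshold = 1000, area_threshold_km2 = 25) {
  stopifnot(all(c("fokontany_id", "n_acs") %in% names(roster)))
  miss <- setdiff(roster$fokontany_id, names(pop))
  if (length(miss))
    stop("roster fokontany without population: ", paste(miss, collapse = ", "))
  miss <- setdiff(roster$fokontany_id, names(areas))
  if (length(miss))
    stop("roster fokontany without area: ", paste(miss, collapse = ", "))
  id <- roster$fokontany_id
  n <- roster$n_acs
  p <- as.numeric(pop[id])
  a <- as.numeric(areas[id])
  per_pop <- ifelse(n > 0, p / n, NA_real_)
  per_area <- ifelse(n > 0, a / n, NA_real_)
  data.frame(
    fokontany_id = id,
    population = p,
    area_km2 = a,
    n_acs = n,
    pop_per_ac = per_pop,
    km2_per_ac = per_area,
    below_pop_threshold = per_pop <= pop_threshold,
    below_area_threshold = per_area <= area_threshold_km2,
    below_both = per_pop <= pop_threshold & per_area <= area_threshold_km2,
    no_acs = n == 0,
    stringsAsFactors = FALSE
  )
}

#' Summarize coverage proportions
#'
#' Proportions of fokontany (with at least one AC) whose per-AC population
#' and surface area fall at or below the thresholds, plus histogram bin
#' counts for the two ratios.
#'
#' @param records data.frame from [coverage_table()].
#' @param pop_breaks,area_breaks histogram breaks for the per-AC ratios.
#' @return list with `prop_below_pop`, `prop_below_area`, `prop_below_both`,
#'   `n`, and `pop_hist` / `area_hist` count tables.
#' @export
coverage_summary <- function(records,
                             pop_breaks = c(0, 250, 500, 1000, 2000, Inf),
                             area_breaks = c(0, 5, 10, 25, 50, Inf)) {
  r <- records[!records$no_acs, ]
  list(
    prop_below_pop = mean(r$below_pop_threshold),
    prop_below_area = mean(r$below_area_threshold),
    prop_below_both = mean(r$below_both),
    n = nrow(r),
    pop_hist = table(cut(r$pop_per_ac, pop_breaks, include.lowest = TRUE)),
    area_hist = table(cut(r$km2_per_ac, area_breaks, include.lowest = TRUE))
  )
}
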