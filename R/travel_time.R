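#' Least accumulated travel time from source cells
#'
#' Exact multi-source Dijkstra on the 8-connected grid graph. The cost of
#' stepping between adjacent cells i and j is `0.5 * (f_i + f_j) * d`
#' minutes, where `f` is the per-cell friction (minutes to traverse one
#' full cell) and `d` is 1 for cardinal and `sqrt(2)` for diagonal moves —
#' the accumulated-cost-surface convention of the standard GIS tools, which
#' makes results bit-reproducible across implementations. Source cells
#' start at 0 minutes.
#'
#' @param friction friction grid (minutes per cell; `Inf`/`NA` =
#'   impassable).
#' @param sources two-column matrix or data.frame of (row, col) cell
#'   indices (1-based, row 1 = north).
#' @return grid of minutes; `Inf` where unreachable, `NA` on impassable
#'   cells.
#' @export
cost_distance <- function(friction, sources) {
  stopifnot(is_grid(friction))
  sources <- as.matrix(sources)
  if (ncol(sources) != 2) stop("sources must be (row, col) pairs")
  storage.mode(sources) <- "integer"
  out <- cost_distance_cpp(friction$values, sources[, 1], sources[, 2])
  grid_like(friction, out)
}

#' Habitable-cell mask from a population grid
#'
#' A cell is habitable — a potential volunteer location — when its
#' population density reaches the threshold. Density is persons per cell
#' divided by the cell area in km^2; at 100 m resolution one person per
#' cell is already 100 persons/km^2.
#'
#' @param population population grid (persons per cell).
#' @param threshold_per_km2 density threshold (default 10 persons/km^2).
#' @return grid of 0/1 indicator values.
#' @export
habitable_mask <- function(population, threshold_per_km2 = 10) {
  stopifnot(is_grid(population), threshold_per_km2 >= 0)
  dens <- population$values / cell_area_km2(population)
  grid_like(population, (dens >= threshold_per_km2) + 0)
}

#' Snap a facility to its grid cell
#'
#' Returns the (row, col) of the cell containing the point; if that cell
#' is impassable, the nearest passable cell within a 3-cell radius
#' (scanning rings outward, deterministic north-first order) is used.
#'
#' @param friction friction grid.
#' @param x,y facility coordinates in the grid CRS.
#' @param max_radius search radius in cells (default 3).
#' @return integer vector (row, col).
#' @export
snap_to_cell <- function(friction, x, y, max_radius = 3) {
  stopifnot(is_grid(friction))
  nr <- nrow(friction$values); nc <- ncol(friction$values)
  cs <- friction$cell_size
  col <- ceiling((x - friction$xll) / cs)
  row <- ceiling((friction$yll + nr * cs - y) / cs)
  col <- min(max(col, 1L), nc); row <- min(max(row, 1L), nr)
  passable <- function(r, c) {
    r >= 1 && r <= nr && c >= 1 && c <= nc &&
      is.finite(friction$values[r, c])
  }
  if (passable(row, col)) return(c(as.integer(row), as.integer(col)))
  for (rad in seq_len(max_radius)) {
    for (dr in -rad:rad) for (dc in -rad:rad) {
      if (max(abs(dr), abs(dc)) != rad) next
      if (passable(row + dr, col + dc))
        return(c(as.integer(row + dr), as.integer(col + dc)))
    }
  }
  stop(sprintf("facility at (%.1f, %.1f) has no passable cell within %d cells",
               x, y, max_radius))
}

#' Travel-time fields from every facility
#'
#' Runs [cost_distance()] once per facility, snapping each facility to its
#' grid cell first.
#'
#' @param friction friction grid.
#' @param facilities data.frame with columns `facility_id`, `x`, `y` (and
#'   typically `kind`, `eligible`).
#' @return named list of travel-time grids, one per `facility_id`.
#' @export
facility_fields <- function(friction, facilities) {
  stopifnot(all(c("facility_id", "x", "y") %in% names(facilities)))
  out <- lapply(seq_len(nrow(facilities)), function(i) {
    src <- snap_to_cell(friction, facilities$x[i], facilities$y[i])
    cost_distance(friction, matrix(src, 1))
  })
  names(out) <- facilities$facility_id
  out
}

#' Fokontany-level mean travel time
#'
#' Averages a facility's travel-time field over the habitable cells whose
#' centers fall inside each fokontany polygon, giving every habitable cell
#' equal weight (each is an equally likely volunteer location). A
#' fokontany with no habitable cell falls back to all of its cells and is
#' flagged.
#'
#' @param field travel-time grid from [cost_distance()].
#' @param mask habitable mask from [habitable_mask()].
#' @param polygons fokontany polygon layer with a `fokontany_id` attribute.
#' @param zones optional precomputed [zone_raster()] for `polygons`
#'   (recomputed otherwise).
#' @return data.frame: `fokontany_id`, `mean_minutes`, `n_habitable_cells`,
#'   `used_fallback`, `unreachable`.
#' @export
fokontany_mean_time <- function(field, mask, polygons, zones = NULL) {
  stopifnot(is_grid(field), is_grid(mask), is_vector_layer(polygons))
  stop_if_misaligned(field, mask)
  if (is.null(zones)) zones <- zone_raster(polygons, field)
  if (all(is.na(zones)))
    stop("polygons fall entirely outside the grid extent")
  ids <- polygons$attrs$fokontany_id
  out <- data.frame(fokontany_id = ids, mean_minutes = NA_real_,
                    n_habitable_cells = 0L, used_fallback = FALSE,
                    unreachable = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    in_zone <- zones == k
    hab <- in_zone & mask$values > 0 & !is.na(field$values)
    fallback <- FALSE
    if (!any(hab, na.rm = TRUE)) {
      hab <- in_zone & !is.na(field$values)
      fallback <- TRUE
      warning("fokontany ", ids[k],
              " has no habitable cell; falling back to all cells")
    }
    vals <- field$values[which(hab)]
    out$mean_minutes[k] <- mean(vals)
    out$n_habitable_cells[k] <- sum(hab, na.rm = TRUE)
    out$used_fallback[k] <- fallback
    out$unreachable[k] <- !is.finite(out$mean_minutes[k])
  }
  out
}

#' Fokontany-by-facility travel-time matrix
#'
#' @param fields named list from [facility_fields()].
#' @param mask habitable mask.
#' @param polygons fokontany polygons.
#' @param zones optional precomputed zone raster.
#' @return numeric matrix, rows = fokontany (named by `fokontany_id`),
#'   columns = facility ids; entries are mean minutes.
#' @export
travel_time_matrix <- function(fields, mask, polygons, zones = NULL) {
  if (is.null(zones)) zones <- zone_raster(polygons, fields[[1]])
  cols <- lapply(fields, function(f)
    suppressWarnings(fokontany_mean_time(f, mask, polygons, zones))$mean_minutes)
  m <- do.call(cbind, cols)
  rownames(m) <- polygons$attrs$fokontany_id
  colnames(m) <- names(fields)
  m
}
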