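#' Land-cover class codes used by the synthetic generator and defaults
#'
#' 1 = bare/open, 2 = cropland, 3 = shrub/grassland, 4 = dense forest,
#' 5 = open water.
#' @export
LANDCOVER_CODES <- c(bare = 1, cropland = 2, shrub = 3, forest = 4, water = 5)

#' Walking-speed table
#'
#' Encodes the pedestrian speed model: a baseline of 5 km/h on bare ground
#' and all road types, reduced speeds on other land-cover classes, and
#' fixed crossing delays for medium (dugout canoe) and large (ferry)
#' rivers. Open water off the river network is impassable (`NA` speed).
#' The class speeds and delays are configuration: field-realistic defaults
#' are shipped, but none are measured constants.
#'
#' @param base_speed_kmh baseline walking speed, km/h (default 5).
#' @param class_speeds named numeric vector, land-cover code -> km/h; `NA`
#'   marks an impassable class. Names are the integer codes as strings.
#' @param road_speed_kmh walking speed on road cells, km/h (default 5:
#'   roads restore the baseline regardless of land cover).
#' @param crossing_delay_min named vector with `medium` and `large` delay
#'   minutes added once per river cell traversed.
#' @param apply_slope_to_roads should the slope factor also apply on road
#'   cells (default TRUE; the road network is largely unpaved paths).
#' @return object of class `chw_speed_table`.
#' @export
speed_table <- function(base_speed_kmh = 5,
                        class_speeds = c(`1` = 5, `2` = 4, `3` = 3.5,
                                         `4` = 2.5, `5` = NA),
                        road_speed_kmh = 5,
                        crossing_delay_min = c(medium = 15, large = 60),
                        apply_slope_to_roads = TRUE) {
  stopifnot(base_speed_kmh > 0, road_speed_kmh > 0,
            all(class_speeds > 0, na.rm = TRUE),
            all(crossing_delay_min >= 0),
            all(c("medium", "large") %in% names(crossing_delay_min)))
  structure(list(base_speed_kmh = base_speed_kmh,
                 class_speeds = class_speeds,
                 road_speed_kmh = road_speed_kmh,
                 crossing_delay_min = crossing_delay_min,
                 apply_slope_to_roads = isTRUE(apply_slope_to_roads)),
            class = "chw_speed_table")
}

#' Read / write a speed table as a YAML config file
#' @param path file path
#' @rdname speed_table_io
#' @export
read_speed_table <- function(path) {
  y <- yaml::read_yaml(path)
  cs <- unlist(y$class_speeds)
  cs <- vapply(cs, function(v) if (is.character(v) && v %in% c("NA", "impassable"))
    NA_real_ else as.numeric(v), numeric(1))
  speed_table(base_speed_kmh = y$base_speed_kmh,
              class_speeds = cs,
              road_speed_kmh = y$road_speed_kmh,
              crossing_delay_min = unlist(y$crossing_delay_min),
              apply_slope_to_roads = y$apply_slope_to_roads)
}

#' @param table a `chw_speed_table`
#' @rdname speed_table_io
#' @export
write_speed_table <- function(table, path) {
  y <- list(base_speed_kmh = table$base_speed_kmh,
            class_speeds = as.list(ifelse(is.na(table$class_speeds),
                                          "impassable", table$class_speeds)),
            road_speed_kmh = table$road_speed_kmh,
            crossing_delay_min = as.list(table$crossing_delay_min),
            apply_slope_to_roads = table$apply_slope_to_roads)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Slope effect on walking speed (Tobler's hiking function)
#'
#' Tobler's empirical model gives walking speed
#' `W(s) = 6 * exp(-3.5 * |s + 0.05|)` km/h as a function of slope `s`
#' (rise over run). The package applies it as a multiplicative factor
#' normalized to flat ground, `W(s) / W(0)`, so the configured baseline
#' speed is preserved exactly on the flat: the factor is 1 at `s = 0` and
#' peaks at `exp(0.175)` (about 1.19) on a gentle -5% downhill. Because
#' cost accumulation here is isotropic, slope enters as a magnitude; the
#' factor is symmetric about `s = -0.05`.
#'
#' @param slope slope (rise/run), any numeric array.
#' @return dimensionless speed multiplier, same shape as `slope`.
#' @export
tobler_factor <- function(slope) {
  exp(-3.5 * (abs(slope + 0.05) - 0.05))
}

#' Slope magnitude from a DEM
#'
#' Horn-style 3x3 central differences on the elevation surface; border
#' cells use one-sided differences (the grid is padded by linear
#' extrapolation, which reduces to one-sided differencing and is exact for
#' planar surfaces).
#'
#' @param dem elevation grid (meters).
#' @return grid of dimensionless slope magnitude (rise/run).
#' @export
slope_grid <- function(dem) {
  stopifnot(is_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z); cs <- dem$cell_size
  if (nr < 2 || nc < 2) return(grid_like(dem, matrix(0, nr, nc)))
  zp <- rbind(2 * z[1, ] - z[2, ], z, 2 * z[nr, ] - z[nr - 1, ])
  zp <- cbind(2 * zp[, 1] - zp[, 2], zp, 2 * zp[, nc] - zp[, nc - 1])
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  nw <- zp[ri - 1, ci - 1]; n_ <- zp[ri - 1, ci]; ne <- zp[ri - 1, ci + 1]
  w_ <- zp[ri, ci - 1];                        e_ <- zp[ri, ci + 1]
  sw <- zp[ri + 1, ci - 1]; s_ <- zp[ri + 1, ci]; se <- zp[ri + 1, ci + 1]
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cs)
  gy <- ((ne + 2 * n_ + nw) - (se + 2 * s_ + sw)) / (8 * cs)
  grid_like(dem, sqrt(gx^2 + gy^2))
}

#' Build the per-cell friction (traversal time) raster
#'
#' Combines land cover, roads, slope and river crossings into minutes to
#' traverse one full cell: walking speed is the road speed on road cells,
#' else the land-cover class speed, multiplied by the Tobler slope factor
#' (on roads only when `apply_slope_to_roads`); traversal time is
#' `(cell_size / 1000) / speed * 60` minutes; medium and large river cells
#' add their crossing delay once. Impassable land cover (open water) off
#' the river network becomes `+Inf`; water cells on the mapped river
#' network stay traversable at the baseline speed, the crossing delay
#' representing the canoe or ferry passage.
#'
#' A flat bare 100 m cell at 5 km/h costs exactly 1.2 minutes.
#'
#' @param landcover land-cover class grid (integer codes).
#' @param roads road presence grid from [rasterize()] (`NA` = no road), or
#'   `NULL` for no roads.
#' @param slope slope magnitude grid from [slope_grid()].
#' @param rivers `chw_rivers` object from [river_grid()], or `NULL`.
#' @param table `chw_speed_table`.
#' @return friction grid in minutes per cell (`+Inf` = impassable).
#' @export
build_friction <- function(landcover, roads = NULL, slope = NULL,
                           rivers = NULL, table = speed_table()) {
  stopifnot(is_grid(landcover), inherits(table, "chw_speed_table"))
  lc <- landcover$values
  classes <- sort(unique(as.vector(lc[!is.na(lc)])))
  known <- as.numeric(names(table$class_speeds))
  if (!all(classes %in% known))
    stop("land-cover class(es) without a speed-table entry: ",
         paste(setdiff(classes, known), collapse = ", "))
  speed <- matrix(table$class_speeds[as.character(lc)],
                  nrow(lc), ncol(lc))
  on_road <- matrix(FALSE, nrow(lc), ncol(lc))
  if (!is.null(roads)) {
    stop_if_misaligned(landcover, roads)
    on_road <- !is.na(roads$values)
    speed[on_road] <- table$road_speed_kmh
  }
  impassable <- is.na(speed) & !on_road
  if (!is.null(rivers)) {
    stop_if_misaligned(landcover, rivers$width_class)
    on_river <- rivers$width_class$values > 0
    # mapped river cells are crossable (delay added below)
    restore <- impassable & on_river
    speed[restore] <- table$base_speed_kmh
    impassable <- impassable & !on_river
  }
  if (!is.null(slope)) {
    stop_if_misaligned(landcover, slope)
    fac <- tobler_factor(slope$values)
    if (table$apply_slope_to_roads) speed <- speed * fac
    else speed[!on_road] <- (speed * fac)[!on_road]
  }
  minutes <- (landcover$cell_size / 1000) / speed * 60
  if (!is.null(rivers)) {
    w <- rivers$width_class$values
    minutes[w == 2] <- minutes[w == 2] + table$crossing_delay_min[["medium"]]
    minutes[w == 3] <- minutes[w == 3] + table$crossing_delay_min[["large"]]
  }
  minutes[impassable] <- Inf
  grid_like(landcover, minutes)
}
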