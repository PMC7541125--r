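#' Create a vector layer
#'
#' Lightweight container for point/polyline/polygon features with an
#' attribute table, mirroring a GeoJSON FeatureCollection. Geometries are
#' stored as two-column coordinate matrices in the same projected CRS as
#' the raster stack.
#'
#' @param geoms list of geometries, each `list(type =
#'   "point"|"linestring"|"polygon", coords = n x 2 matrix)`. Polygons are
#'   single rings; the closing vertex may be present or absent.
#' @param attrs data.frame of feature attributes (one row per geometry).
#' @param crs_id projected CRS identifier; must match the raster stack.
#' @export
vector_layer <- function(geoms, attrs = NULL, crs_id = "local-meters") {
  stopifnot(is.list(geoms))
  if (is.null(attrs)) attrs <- data.frame(row.names = seq_along(geoms))
  stopifnot(nrow(attrs) == length(geoms))
  for (g in geoms) {
    stopifnot(g$type %in% c("point", "linestring", "polygon"),
              is.matrix(g$coords), ncol(g$coords) == 2)
  }
  structure(list(geoms = geoms, attrs = attrs, crs_id = as.character(crs_id)),
            class = "chw_vector")
}

#' @export
is_vector_layer <- function(x) inherits(x, "chw_vector")

#' @export
print.chw_vector <- function(x, ...) {
  types <- vapply(x$geoms, `[[`, "", "type")
  cat(sprintf("<chw_vector> %d features (%s), crs '%s', attrs: %s\n",
              length(x$geoms),
              paste(sprintf("%d %s", table(types), names(table(types))),
                    collapse = ", "),
              x$crs_id, paste(names(x$attrs), collapse = ", ")))
  invisible(x)
}

close_ring <- function(m) {
  if (!isTRUE(all.equal(m[1, ], m[nrow(m), ]))) m <- rbind(m, m[1, ])
  m
}

open_ring <- function(m) {
  if (nrow(m) > 1 && isTRUE(all.equal(m[1, ], m[nrow(m), ])))
    m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Planar polygon area (shoelace formula)
#'
#' @param coords n x 2 vertex matrix (closed or open ring).
#' @return absolute area in squared CRS units (m^2).
#' @export
polygon_area <- function(coords) {
  m <- open_ring(coords)
  x <- m[, 1]; y <- m[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Areas of all polygon features, in km^2
#' @param layer polygon vector layer
#' @export
layer_areas_km2 <- function(layer) {
  stopifnot(is_vector_layer(layer))
  vapply(layer$geoms, function(g) {
    if (g$type != "polygon") return(NA_real_)
    polygon_area(g$coords) / 1e6
  }, numeric(1))
}

#' Read a GeoJSON FeatureCollection
#'
#' Supports Point, LineString and Polygon geometries (outer ring only;
#' holes are not used by this pipeline). The CRS identifier is taken from a
#' legacy named `crs` member when present, else `crs_id`.
#'
#' @param path file path.
#' @param crs_id fallback CRS identifier.
#' @return a `chw_vector`.
#' @export
read_geojson <- function(path, crs_id = "local-meters") {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$type) || j$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection: ", path)
  if (!is.null(j$crs$properties$name)) crs_id <- j$crs$properties$name
  geoms <- list(); rows <- list()
  for (f in j$features) {
    gt <- f$geometry$type
    co <- f$geometry$coordinates
    g <- switch(gt,
      Point = list(type = "point",
                   coords = matrix(unlist(co), ncol = 2, byrow = TRUE)),
      LineString = list(type = "linestring",
                        coords = do.call(rbind, lapply(co, unlist))),
      Polygon = list(type = "polygon",
                     coords = open_ring(do.call(rbind, lapply(co[[1]], unlist)))),
      stop("unsupported GeoJSON geometry type: ", gt)
    )
    geoms[[length(geoms) + 1L]] <- g
    rows[[length(rows) + 1L]] <-
      as.data.frame(lapply(f$properties, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)
  }
  attrs <- if (length(rows)) do.call(rbind, rows) else NULL
  vector_layer(geoms, attrs, crs_id)
}

#' Write a vector layer as GeoJSON
#'
#' @param layer vector layer.
#' @param path output path.
#' @param digits coordinate precision (significant digits).
#' @export
write_geojson <- function(layer, path, digits = 10) {
  stopifnot(is_vector_layer(layer))
  feats <- lapply(seq_along(layer$geoms), function(k) {
    g <- layer$geoms[[k]]
    coords <- signif(g$coords, digits)
    geom <- switch(g$type,
      point = list(type = "Point", coordinates = as.numeric(coords[1, ])),
      linestring = list(type = "LineString",
                        coordinates = lapply(seq_len(nrow(coords)),
                                             function(i) as.numeric(coords[i, ]))),
      polygon = {
        ring <- close_ring(coords)
        list(type = "Polygon",
             coordinates = list(lapply(seq_len(nrow(ring)),
                                       function(i) as.numeric(ring[i, ]))))
      })
    props <- as.list(layer$attrs[k, , drop = FALSE])
    props <- lapply(props, function(v) if (is.factor(v)) as.character(v) else v)
    list(type = "Feature", properties = props, geometry = geom)
  })
  fc <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = layer$crs_id)),
    features = feats
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Which polygon contains each cell center
#'
#' Assigns every cell of `reference` to the first polygon feature whose
#' interior or boundary contains the cell center (features are disjoint in
#' this pipeline, so order does not matter). Cells outside all polygons get
#' `NA`.
#'
#' @param layer polygon layer.
#' @param reference grid defining the cells.
#' @return integer matrix of feature indices (same shape as the grid).
#' @export
zone_raster <- function(layer, reference) {
  stopifnot(is_vector_layer(layer), is_grid(reference))
  if (layer$crs_id != reference$crs_id)
    stop("CRS mismatch between layer and reference grid")
  ctr <- cell_centers(reference)
  nr <- length(ctr$y); nc <- length(ctr$x)
  px <- rep(ctr$x, each = nr)
  py <- rep(ctr$y, times = nc)
  zone <- matrix(NA_integer_, nr, nc)
  for (k in seq_along(layer$geoms)) {
    g <- layer$geoms[[k]]
    if (g$type != "polygon") next
    ring <- open_ring(g$coords)
    bb <- apply(ring, 2, range)
    cand <- which(is.na(zone) &
                  px >= bb[1, 1] & px <= bb[2, 1] &
                  py >= bb[1, 2] & py <= bb[2, 2])
    if (!length(cand)) next
    hit <- sp::point.in.polygon(px[cand], py[cand], ring[, 1], ring[, 2]) > 0
    zone[cand[hit]] <- k
  }
  zone
}

point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Burn vector features into a raster
#'
#' Points burn the cell containing them; polygons burn every cell whose
#' center lies inside; polylines burn every cell whose center lies within
#' half a cell size of the line (a supercover-like rule that keeps burned
#' roads 8-connected for the cost graph). Cells touched by no feature are
#' `NA`.
#'
#' @param layer vector layer.
#' @param reference grid defining geometry of the output.
#' @param burn_value_field attribute column supplying per-feature values,
#'   or `NULL` to use `burn_value` for all features.
#' @param burn_value constant burn value (default 1).
#' @return a grid aligned with `reference`.
#' @export
rasterize <- function(layer, reference, burn_value_field = NULL, burn_value = 1) {
  stopifnot(is_vector_layer(layer), is_grid(reference))
  if (layer$crs_id != reference$crs_id)
    stop("CRS mismatch between layer and reference grid")
  if (!length(layer$geoms)) {
    warning("empty layer: rasterize returns an all-nodata grid")
    return(grid_like(reference, matrix(NA_real_, nrow(reference$values),
                                       ncol(reference$values))))
  }
  vals <- if (is.null(burn_value_field)) rep(burn_value, length(layer$geoms))
          else as.numeric(layer$attrs[[burn_value_field]])
  ctr <- cell_centers(reference)
  nr <- length(ctr$y); nc <- length(ctr$x); cs <- reference$cell_size
  out <- matrix(NA_real_, nr, nc)
  half <- cs / 2 + 1e-9
  col_of <- function(x) pmin(pmax(ceiling((x - reference$xll) / cs), 1L), nc)
  row_of <- function(y) pmin(pmax(ceiling((reference$yll + nr * cs - y) / cs), 1L), nr)
  for (k in seq_along(layer$geoms)) {
    g <- layer$geoms[[k]]
    if (g$type == "point") {
      x <- g$coords[1, 1]; y <- g$coords[1, 2]
      if (x >= reference$xll && x <= reference$xll + nc * cs &&
          y >= reference$yll && y <= reference$yll + nr * cs)
        out[row_of(y), col_of(x)] <- vals[k]
    } else if (g$type == "linestring") {
      co <- g$coords
      for (s in seq_len(nrow(co) - 1)) {
        xr <- range(co[s:(s + 1), 1]); yr <- range(co[s:(s + 1), 2])
        cols <- which(ctr$x >= xr[1] - half & ctr$x <= xr[2] + half)
        rows <- which(ctr$y >= yr[1] - half & ctr$y <= yr[2] + half)
        if (!length(cols) || !length(rows)) next
        px <- rep(ctr$x[cols], each = length(rows))
        py <- rep(ctr$y[rows], times = length(cols))
        d <- point_segment_dist(px, py, co[s, 1], co[s, 2],
                                co[s + 1, 1], co[s + 1, 2])
        hit <- matrix(d <= half, length(rows), length(cols))
        out[rows, cols][hit] <- vals[k]
      }
    } else { # polygon
      ring <- open_ring(g$coords)
      bb <- apply(ring, 2, range)
      cols <- which(ctr$x >= bb[1, 1] & ctr$x <= bb[2, 1])
      rows <- which(ctr$y >= bb[1, 2] & ctr$y <= bb[2, 2])
      if (!length(cols) || !length(rows)) next
      px <- rep(ctr$x[cols], each = length(rows))
      py <- rep(ctr$y[rows], times = length(cols))
      hit <- matrix(sp::point.in.polygon(px, py, ring[, 1], ring[, 2]) > 0,
                    length(rows), length(cols))
      out[rows, cols][hit] <- vals[k]
    }
  }
  grid_like(reference, out)
}
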