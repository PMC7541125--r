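#' @useDynLib chwaccess, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Create a north-up raster grid
#'
#' The grid is the carrier type for every raster in the pipeline (elevation,
#' land cover, population, friction, travel time). Values are stored as a
#' numeric matrix in row-major, north-up order: `values[1, 1]` is the
#' north-west cell. The transform is axis-aligned (no rotation or shear)
#' with square cells in a projected, meter-unit CRS. Missing cells are `NA`
#' in memory; `nodata` is the sentinel used on disk.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll coordinates of the lower-left (south-west) corner of the
#'   grid extent, in meters.
#' @param cell_size cell edge length in meters (> 0; cells are square).
#' @param nodata sentinel value used when writing to disk.
#' @param crs_id free-text identifier of the projected CRS. All layers in
#'   one run must agree.
#' @return an object of class `chw_grid`.
#' @export
grid_new <- function(values, xll = 0, yll = 0, cell_size,
                     nodata = -9999, crs_id = "local-meters") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cell_size = as.numeric(cell_size), nodata = as.numeric(nodata),
         crs_id = as.character(crs_id)),
    class = "chw_grid"
  )
}

#' @export
is_grid <- function(x) inherits(x, "chw_grid")

#' @export
dim.chw_grid <- function(x) dim(x$values)

#' @export
print.chw_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<chw_grid> %d x %d cells, %.6g m cell, origin (%.6g, %.6g), crs '%s'\n",
              d[1], d[2], x$cell_size, x$xll, x$yll, x$crs_id))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("  values: [%.6g, %.6g], %d NA\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' Grid with same geometry, new values
#' @param g template grid
#' @param values replacement matrix (same shape)
#' @export
grid_like <- function(g, values) {
  stopifnot(is_grid(g))
  if (!is.matrix(values)) values <- matrix(values, nrow(g$values), ncol(g$values))
  stopifnot(identical(dim(values), dim(g$values)))
  out <- g
  storage.mode(values) <- "double"
  out$values <- values
  out
}

#' Cell-center coordinates
#'
#' @param g grid
#' @return list with `x` (length ncol, west to east) and `y` (length nrow,
#'   north to south), matching the matrix layout.
#' @export
cell_centers <- function(g) {
  stopifnot(is_grid(g))
  nr <- nrow(g$values); nc <- ncol(g$values); cs <- g$cell_size
  list(x = g$xll + (seq_len(nc) - 0.5) * cs,
       y = g$yll + (nr - seq_len(nr) + 0.5) * cs)
}

#' Cell area in square kilometers
#' @param g grid
#' @export
cell_area_km2 <- function(g) (g$cell_size / 1000)^2

grid_same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cell_size - b$cell_size) < tol && a$crs_id == b$crs_id
}

stop_if_misaligned <- function(..., what = "grids") {
  gs <- list(...)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!grid_same_geometry(ref, g))
      stop(what, " are not aligned: shape/transform/crs differ; run align_stack() first")
  }
  invisible(TRUE)
}

#' Read a single-band raster from an ESRI ASCII grid file
#'
#' ESRI ASCII grid (`.asc`) is the plain-text raster interchange format:
#' a short header (`ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter`, `cellsize`, `nodata_value`) followed by the cell
#' values, north row first. The format can only express an axis-aligned,
#' square-cell (north-up) transform; files carrying the non-square `dx`/`dy`
#' extension are rejected.
#'
#' @param path file path.
#' @param expected_cell_size if not `NULL`, error unless the file's cell
#'   size matches to 1e-6 m — a guard for pipelines that assume one
#'   resolution.
#' @param crs_id CRS identifier to attach (the format itself stores none).
#'   Must describe a projected, meter-unit CRS; geographic (degree) inputs
#'   must be reprojected before entering the pipeline.
#' @return a `chw_grid`.
#' @export
read_grid <- function(path, expected_cell_size = NULL, crs_id = "local-meters") {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing ncols/nrows header): ", path)
  if (any(c("dx", "dy") %in% names(hdr)))
    stop("non-square or non-north-up raster: dx/dy headers are not supported")
  if (!"cellsize" %in% names(hdr))
    stop("non-north-up raster: missing square 'cellsize' header")
  cs <- hdr$cellsize
  if (cs <= 0) stop("invalid cellsize: ", cs)
  if (!is.null(expected_cell_size) && abs(cs - expected_cell_size) > 1e-6)
    stop(sprintf("cell size %.6g m does not match expected %.6g m", cs,
                 expected_cell_size))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2 else 0
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("raster body has %d values, expected %d", length(vals), nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_new(m, xll, yll, cs, nodata, crs_id)
}

#' Write a grid to an ESRI ASCII grid file
#'
#' Round-trips with [read_grid()]: values (at the written precision),
#' transform and nodata survive a write/read cycle.
#'
#' @param g grid.
#' @param path output path (conventionally `.asc`).
#' @param digits significant digits for cell values (default 15, enough for
#'   a lossless double round-trip in practice).
#' @export
write_grid <- function(g, path, digits = 15) {
  stopifnot(is_grid(g))
  m <- g$values
  m[is.na(m)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10f", g$xll),
    sprintf("yllcorner %.10f", g$yll),
    sprintf("cellsize %.10f", g$cell_size),
    sprintf("nodata_value %.10g", g$nodata)
  )
  body <- apply(m, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Resample one grid onto the geometry of a reference grid
#'
#' @param g source grid.
#' @param reference grid supplying the target shape and transform.
#' @param method `"nearest"` (categorical layers) or `"bilinear"`
#'   (continuous layers). Bilinear interpolates between the four
#'   surrounding source cell centers; at the source border it clamps to the
#'   edge value.
#' @return a grid aligned to `reference`.
#' @export
resample_to <- function(g, reference, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is_grid(g), is_grid(reference))
  if (g$crs_id != reference$crs_id)
    stop("CRS mismatch: '", g$crs_id, "' vs '", reference$crs_id, "'")
  ctr <- cell_centers(reference)
  nrS <- nrow(g$values); ncS <- ncol(g$values); cs <- g$cell_size
  topS <- g$yll + nrS * cs
  # source extent overlap check
  if (min(ctr$x) > g$xll + ncS * cs || max(ctr$x) < g$xll ||
      min(ctr$y) > topS || max(ctr$y) < g$yll)
    stop("disjoint extents: source grid does not overlap reference")
  nrR <- nrow(reference$values); ncR <- ncol(reference$values)
  out <- matrix(NA_real_, nrR, ncR)
  if (method == "nearest") {
    jj <- pmin(pmax(ceiling((ctr$x - g$xll) / cs), 1L), ncS)
    ii <- pmin(pmax(ceiling((topS - ctr$y) / cs), 1L), nrS)
    inx <- ctr$x >= g$xll & ctr$x <= g$xll + ncS * cs
    iny <- ctr$y >= g$yll & ctr$y <= topS
    out <- g$values[cbind(rep(ii, times = ncR), rep(jj, each = nrR))]
    dim(out) <- c(nrR, ncR)
    out[!iny, ] <- NA_real_
    out[, !inx] <- NA_real_
  } else {
    # fractional 0-based position between source cell centers
    u <- (ctr$x - g$xll) / cs - 0.5          # along columns
    v <- (topS - ctr$y) / cs - 0.5           # along rows (from north)
    j0 <- pmin(pmax(floor(u), 0), ncS - 1e-9)
    i0 <- pmin(pmax(floor(v), 0), nrS - 1e-9)
    fx <- pmin(pmax(u - j0, 0), 1)
    fy <- pmin(pmax(v - i0, 0), 1)
    j0 <- pmin(pmax(as.integer(j0), 0L), ncS - 1L)
    i0 <- pmin(pmax(as.integer(i0), 0L), nrS - 1L)
    j1 <- pmin(j0 + 1L, ncS - 1L)
    i1 <- pmin(i0 + 1L, nrS - 1L)
    for (r in seq_len(nrR)) {
      a <- g$values[cbind(i0[r] + 1L, j0 + 1L)]
      b <- g$values[cbind(i0[r] + 1L, j1 + 1L)]
      cc <- g$values[cbind(i1[r] + 1L, j0 + 1L)]
      d <- g$values[cbind(i1[r] + 1L, j1 + 1L)]
      out[r, ] <- (a * (1 - fx) + b * fx) * (1 - fy[r]) +
                  (cc * (1 - fx) + d * fx) * fy[r]
    }
    inx <- ctr$x >= g$xll & ctr$x <= g$xll + ncS * cs
    iny <- ctr$y >= g$yll & ctr$y <= topS
    out[!iny, ] <- NA_real_
    out[, !inx] <- NA_real_
  }
  res <- reference
  res$values <- out
  res$nodata <- g$nodata
  res
}

#' Align a raster stack onto a reference geometry
#'
#' Brings heterogeneous-resolution inputs (e.g., a 30 m elevation model and
#' a 300 m land-cover product) onto the single analysis grid. Categorical
#' layers should use nearest-neighbour, continuous layers bilinear
#' resampling. Aligning an already-aligned grid is a no-op (values pass
#' through unchanged).
#'
#' @param grids list of grids.
#' @param reference target geometry.
#' @param resampling character vector, one of `"nearest"`/`"bilinear"` per
#'   grid (recycled if length 1). Default `"bilinear"`.
#' @return list of grids, each matching `reference`'s shape and transform.
#' @export
align_stack <- function(grids, reference, resampling = "bilinear") {
  stopifnot(is.list(grids))
  resampling <- rep_len(resampling, length(grids))
  lapply(seq_along(grids), function(k) {
    g <- grids[[k]]
    if (grid_same_geometry(g, reference)) return(g)
    resample_to(g, reference, resampling[k])
  })
}
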