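# Neighbour convention shared across the package: codes 1..8 are
# N, NE, E, SE, S, SW, W, NW; 0 means "drains off-grid" (outlet).
D8_DR <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
D8_DC <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Fill depressions in a DEM
#'
#' Priority-flood filling with a small epsilon gradient: the output surface
#' has no internal pits and no flats, so every cell has a strictly
#' descending 8-neighbour path to the grid border and D8 routing is
#' well-defined. Flats created by filling are resolved by the epsilon
#' increments, which impose a gradient toward the spill outlet.
#'
#' @param dem elevation grid (meters).
#' @param eps gradient imposed across filled flats, in meters per cell
#'   step (default 1e-4 m — negligible relative to real relief).
#' @return filled elevation grid.
#' @export
fill_depressions <- function(dem, eps = 1e-4) {
  stopifnot(is_grid(dem))
  if (anyNA(dem$values)) stop("DEM contains NA cells; fill requires a complete surface")
  grid_like(dem, fill_depressions_cpp(dem$values, eps))
}

#' D8 flow directions
#'
#' Each cell drains to the steepest-descent neighbour of its eight,
#' where descent is measured as drop divided by center distance (diagonal
#' neighbours are `cell_size * sqrt(2)` away, so a cardinal neighbour wins
#' a tie on equal drop). Remaining ties break deterministically in the
#' fixed neighbour order N, NE, E, SE, S, SW, W, NW. Cells with no lower
#' in-grid neighbour must lie on the border (they drain off-grid, code 0);
#' an interior cell with none indicates an unfilled pit or flat.
#'
#' @param dem depression-filled elevation grid.
#' @return grid of direction codes 0..8.
#' @export
d8_flow_direction <- function(dem) {
  stopifnot(is_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  best_g <- matrix(0, nr, nc)
  best_k <- matrix(0L, nr, nc)
  for (k in 1:8) {
    zn <- matrix(NA_real_, nr, nc)
    rs <- (1 - min(0, D8_DR[k])):(nr - max(0, D8_DR[k]))
    cs <- (1 - min(0, D8_DC[k])):(nc - max(0, D8_DC[k]))
    zn[rs, cs] <- z[rs + D8_DR[k], cs + D8_DC[k]]
    d <- if (D8_DR[k] != 0 && D8_DC[k] != 0) sqrt(2) else 1
    grad <- (z - zn) / d
    upd <- !is.na(grad) & grad > best_g   # strict: earlier k wins ties
    best_g[upd] <- grad[upd]
    best_k[upd] <- k
  }
  none <- best_k == 0L
  interior <- matrix(TRUE, nr, nc)
  interior[1, ] <- interior[nr, ] <- FALSE
  interior[, 1] <- interior[, nc] <- FALSE
  if (any(none & interior))
    stop("unresolved flat or pit at interior cells; run fill_depressions() first")
  grid_like(dem, best_k + 0)   # numeric storage
}

d8_receivers <- function(direction) {
  d <- direction$values
  nr <- nrow(d); nc <- ncol(d); n <- nr * nc
  recv <- rep(NA_integer_, n)
  has <- which(d > 0)
  if (length(has)) {
    k <- as.integer(d[has])
    r <- ((has - 1L) %% nr) + 1L
    c <- ((has - 1L) %/% nr) + 1L
    r2 <- r + D8_DR[k]; c2 <- c + D8_DC[k]
    if (any(r2 < 1L | r2 > nr | c2 < 1L | c2 > nc))
      stop("direction grid points off the grid edge")
    recv[has] <- (c2 - 1L) * nr + r2
  }
  recv
}

# Topological (Kahn) order of the flow forest; errors on cycles.
d8_topo_order <- function(recv, n) {
  indeg <- tabulate(recv[!is.na(recv)], n)
  queue <- integer(n)
  tail <- 0L
  zero <- which(indeg == 0L)
  queue[seq_along(zero)] <- zero
  tail <- length(zero)
  head <- 1L
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    j <- recv[i]
    if (!is.na(j)) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) { tail <- tail + 1L; queue[tail] <- j }
    }
  }
  if (tail < n) stop("cycle in flow-direction grid (corrupt input)")
  queue
}

#' D8 flow accumulation
#'
#' Counts, for every cell, the number of cells (itself included) whose
#' flow path passes through it. Computed in topological order over the
#' drainage forest; a cycle in the direction grid is an error.
#'
#' @param direction D8 direction grid from [d8_flow_direction()].
#' @return grid of upslope cell counts (>= 1 everywhere).
#' @export
flow_accumulation <- function(direction) {
  stopifnot(is_grid(direction))
  d <- direction$values
  nr <- nrow(d); nc <- ncol(d); n <- nr * nc
  recv <- d8_receivers(direction)
  ord <- d8_topo_order(recv, n)
  acc <- rep(1, n)
  for (i in ord) {
    j <- recv[i]
    if (!is.na(j)) acc[j] <- acc[j] + acc[i]
  }
  grid_like(direction, matrix(acc, nr, nc))
}

#' Strahler stream order
#'
#' Stream cells are those with flow accumulation at or above
#' `stream_threshold`. A stream cell with no stream tributaries has order
#' 1; at a junction the order is the maximum tributary order, incremented
#' by one when at least two tributaries attain that maximum. Non-stream
#' cells are 0.
#'
#' @param direction D8 direction grid.
#' @param accumulation accumulation grid from [flow_accumulation()].
#' @param stream_threshold accumulation (cell count) at which a cell
#'   becomes a stream; default 50 cells.
#' @return grid of Strahler orders (0 off-stream).
#' @export
strahler_order <- function(direction, accumulation, stream_threshold = 50) {
  stopifnot(is_grid(direction), is_grid(accumulation))
  stop_if_misaligned(direction, accumulation)
  d <- direction$values
  nr <- nrow(d); nc <- ncol(d); n <- nr * nc
  stream <- as.vector(accumulation$values) >= stream_threshold
  recv <- d8_receivers(direction)
  ord <- d8_topo_order(recv, n)
  max_in <- rep(0L, n)
  n_max <- rep(0L, n)
  order_out <- rep(0L, n)
  for (i in ord) {
    if (stream[i]) {
      order_out[i] <- if (max_in[i] == 0L) 1L else
        max_in[i] + as.integer(n_max[i] >= 2L)
      j <- recv[i]
      if (!is.na(j) && stream[j]) {
        if (order_out[i] > max_in[j]) {
          max_in[j] <- order_out[i]; n_max[j] <- 1L
        } else if (order_out[i] == max_in[j]) {
          n_max[j] <- n_max[j] + 1L
        }
      }
    }
  }
  grid_like(direction, matrix(as.numeric(order_out), nr, nc))
}

#' Default Strahler-order to river-width-class map
#'
#' Orders up to `small` are small streams (fordable, no crossing delay);
#' orders up to `medium` are medium rivers (20-60 m wide, dugout-canoe
#' crossing); larger orders are large rivers (over 60 m, ferry crossing).
#' The order-to-width calibration is a configuration choice, not a
#' measured quantity.
#' @export
default_width_map <- function() list(small = 3, medium = 5)

#' River width classes from Strahler order
#'
#' @param strahler Strahler order grid.
#' @param class_map list with `small` and `medium` order cut-offs (see
#'   [default_width_map()]).
#' @return grid coded 0 = none, 1 = small, 2 = medium, 3 = large.
#' @export
width_class <- function(strahler, class_map = default_width_map()) {
  stopifnot(is_grid(strahler), class_map$small < class_map$medium)
  s <- strahler$values
  w <- matrix(0, nrow(s), ncol(s))
  w[s > 0 & s <= class_map$small] <- 1
  w[s > class_map$small & s <= class_map$medium] <- 2
  w[s > class_map$medium] <- 3
  grid_like(strahler, w)
}

#' Derive the full river network from a DEM
#'
#' Fills depressions, routes D8 flow, accumulates, orders streams and
#' classifies widths in one call.
#'
#' @param dem elevation grid (need not be pre-filled).
#' @param stream_threshold accumulation threshold in cells (default 50 at
#'   100 m resolution, i.e. 0.5 km^2 of upslope area).
#' @param class_map Strahler-order to width-class map.
#' @return object of class `chw_rivers`: list with grids `direction`,
#'   `accumulation`, `strahler`, `width_class` and the `filled` DEM.
#' @export
river_grid <- function(dem, stream_threshold = 50,
                       class_map = default_width_map()) {
  filled <- fill_depressions(dem)
  dir <- d8_flow_direction(filled)
  acc <- flow_accumulation(dir)
  str <- strahler_order(dir, acc, stream_threshold)
  wid <- width_class(str, class_map)
  structure(list(direction = dir, accumulation = acc, strahler = str,
                 width_class = wid, filled = filled,
                 stream_threshold = stream_threshold),
            class = "chw_rivers")
}

#' @export
print.chw_rivers <- function(x, ...) {
  ns <- sum(x$strahler$values > 0)
  cat(sprintf("<chw_rivers> %d stream cells (threshold %g), max order %g\n",
              ns, x$stream_threshold, max(x$strahler$values)))
  invisible(x)
}
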