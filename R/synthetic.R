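#' Specification of a synthetic study area
#'
#' Defines the conditions the generator emulates: a rural district pair
#' with clustered settlements on a dissected terrain, a road network
#' linking settlements, Voronoi fokontany around settlement cores,
#' health centers (CSB) and supply points (PA) hosted by a subset of
#' settlements, and a volunteer roster of about two ACs per fokontany.
#' All randomness derives from `seed`; the same spec yields byte-identical
#' outputs.
#'
#' @param rows,cols grid shape (default 200 x 200).
#' @param cell_size cell edge, meters (default 100).
#' @param seed integer RNG seed.
#' @param n_settlements number of settlement cores (default 30).
#' @param settlement_peak_density peak population density at a settlement
#'   core, persons/km^2 (default 1200; sizes vary by a lognormal factor).
#' @param settlement_size_sdlog sd(log) of the per-settlement size factor.
#' @param settlement_kernel_sd_m Gaussian kernel sd, meters (default 400).
#' @param min_separation_cells minimum Chebyshev distance between
#'   settlement cores, cells.
#' @param border_margin_cells keep settlement cores at least this far from
#'   the grid border.
#' @param relief_amplitude_m amplitude of the random terrain component,
#'   meters; 0 gives a plane equal to the trend.
#' @param correlation_length_cells correlation length of the terrain
#'   noise.
#' @param trend_amplitude_m north-to-south elevation drop of the planar
#'   trend, meters (drainage exits the southern border).
#' @param landcover_weights mixture weights for bare / cropland / shrub /
#'   forest cover (no open water by default, keeping the extent fully
#'   traversable).
#' @param landcover_correlation_cells patch size of the land-cover field.
#' @param csb_fraction,pa_fraction fraction of settlements hosting a CSB /
#'   a PA.
#' @param n_communes number of communes (settlement clusters); communes
#'   without a PA-hosting settlement have no PA, and their fokontany are
#'   excluded from PA scenarios.
#' @param acs_probs probability of a fokontany having 1, 2, ... ACs;
#'   default concentrates on 2 (92%), mirroring a deployment guideline of
#'   2 volunteers per fokontany with occasional extras.
#' @param misassign_csb,misassign_pa probability that a fokontany is
#'   assigned a facility other than its closest one (defaults 0.31 /
#'   0.25).
#' @param stream_threshold flow-accumulation threshold (cells) for stream
#'   delineation.
#' @return object of class `chw_landscape_spec`.
#' @export
landscape_spec <- function(rows = 200, cols = 200, cell_size = 100,
                           seed = 1,
                           n_settlements = 30,
                           settlement_peak_density = 1200,
                           settlement_size_sdlog = 0.6,
                           settlement_kernel_sd_m = 400,
                           min_separation_cells = 8,
                           border_margin_cells = 6,
                           relief_amplitude_m = 300,
                           correlation_length_cells = 15,
                           trend_amplitude_m = 150,
                           landcover_weights = c(bare = 0.15, cropland = 0.35,
                                                 shrub = 0.30, forest = 0.20),
                           landcover_correlation_cells = 10,
                           csb_fraction = 0.2,
                           pa_fraction = 0.17,
                           n_communes = 6,
                           acs_probs = c(`1` = 0.01, `2` = 0.92, `3` = 0.03,
                                         `4` = 0.02, `5` = 0.01, `6` = 0.01),
                           misassign_csb = 0.31,
                           misassign_pa = 0.25,
                           stream_threshold = 50) {
  stopifnot(rows >= 10, cols >= 10, cell_size > 0, n_settlements >= 2,
            relief_amplitude_m >= 0, abs(sum(acs_probs) - 1) < 1e-8,
            misassign_csb >= 0, misassign_csb <= 1,
            misassign_pa >= 0, misassign_pa <= 1,
            all(landcover_weights >= 0), sum(landcover_weights) > 0,
            names(landcover_weights) %in% names(LANDCOVER_CODES))
  n_csb <- max(2L, round(csb_fraction * n_settlements))
  n_pa <- max(1L, round(pa_fraction * n_settlements))
  if (n_settlements < n_csb || n_settlements < n_pa)
    stop("fewer settlements than requested facilities")
  spec <- as.list(environment())
  structure(spec, class = "chw_landscape_spec")
}

#' @export
print.chw_landscape_spec <- function(x, ...) {
  cat(sprintf("<chw_landscape_spec> %dx%d @ %gm, seed %d, %d settlements, %d CSB, %d PA\n",
              x$rows, x$cols, x$cell_size, x$seed, x$n_settlements,
              x$n_csb, x$n_pa))
  invisible(x)
}

# Run code with a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# Stationary Gaussian random field: white noise smoothed by a circular
# Gaussian kernel via FFT, normalized to zero mean and unit sd.
smooth_field <- function(nr, nc, corr_len) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  K <- outer(exp(-dr^2 / (2 * corr_len^2)), exp(-dc^2 / (2 * corr_len^2)))
  f <- Re(stats::fft(stats::fft(w) * stats::fft(K), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / stats::sd(f)
}

#' Generate the synthetic elevation model
#'
#' A planar trend falling from the northern to the southern border plus a
#' seeded correlated noise field, depression-filled so the D8 river
#' network is well-defined (every cell has a monotone descending path to
#' the border). With `relief_amplitude_m = 0` the output is exactly the
#' planar trend.
#'
#' @param spec a [landscape_spec()].
#' @return filled elevation grid (meters).
#' @export
make_dem <- function(spec) {
  nr <- spec$rows; nc <- spec$cols
  ry <- (seq_len(nr) - 1) / (nr - 1)
  trend <- matrix(spec$trend_amplitude_m * (1 - ry), nr, nc)
  z <- trend
  if (spec$relief_amplitude_m > 0) {
    noise <- with_seed(spec$seed + 11L,
                       smooth_field(nr, nc, spec$correlation_length_cells))
    z <- z + spec$relief_amplitude_m / 4 * noise
  }
  fill_depressions(grid_new(z, 0, 0, spec$cell_size))
}

#' Generate the synthetic land-cover grid
#'
#' A correlated random field cut at the quantiles of the class mixture
#' weights, yielding contiguous patches of bare ground, cropland, shrub
#' and forest (codes in [LANDCOVER_CODES]).
#'
#' @param spec a [landscape_spec()].
#' @return land-cover class grid.
#' @export
make_landcover <- function(spec) {
  nr <- spec$rows; nc <- spec$cols
  u <- with_seed(spec$seed + 23L,
                 smooth_field(nr, nc, spec$landcover_correlation_cells))
  w <- spec$landcover_weights / sum(spec$landcover_weights)
  qs <- stats::quantile(u, cumsum(w)[-length(w)])
  cls <- findInterval(u, qs) + 1L
  codes <- LANDCOVER_CODES[names(w)]
  grid_new(matrix(codes[cls], nr, nc), 0, 0, spec$cell_size)
}

#' Place settlement cores
#'
#' Samples settlement cells with probability decreasing in elevation
#' (valley-bottom bias), enforcing a minimum separation and a border
#' margin; draws a lognormal size factor per settlement.
#'
#' @param spec a [landscape_spec()].
#' @param dem elevation grid from [make_dem()].
#' @return data.frame: `settlement_id`, `row`, `col`, `x`, `y`,
#'   `size_mult`.
#' @export
make_settlements <- function(spec, dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z); cs <- dem$cell_size
  m <- spec$border_margin_cells
  ok <- matrix(FALSE, nr, nc)
  ok[(m + 1):(nr - m), (m + 1):(nc - m)] <- TRUE
  rng <- max(z) - min(z)
  wgt <- exp(-(z - min(z)) / (0.3 * max(rng, 1)))
  with_seed(spec$seed + 37L, {
    rows <- integer(0); cols <- integer(0)
    cand <- which(ok)
    for (i in seq_len(spec$n_settlements)) {
      if (!length(cand)) stop("cannot place ", spec$n_settlements,
                              " settlements with the requested separation")
      pick <- cand[sample.int(length(cand), 1, prob = wgt[cand])]
      r <- ((pick - 1L) %% nr) + 1L
      c <- ((pick - 1L) %/% nr) + 1L
      rows <- c(rows, r); cols <- c(cols, c)
      pr <- ((cand - 1L) %% nr) + 1L
      pc <- ((cand - 1L) %/% nr) + 1L
      cand <- cand[pmax(abs(pr - r), abs(pc - c)) >= spec$min_separation_cells]
    }
    mult <- stats::rlnorm(spec$n_settlements, 0, spec$settlement_size_sdlog)
  })
  data.frame(settlement_id = seq_len(spec$n_settlements),
             row = rows, col = cols,
             x = dem$xll + (cols - 0.5) * cs,
             y = dem$yll + (nr - rows + 0.5) * cs,
             size_mult = mult)
}

#' Generate the synthetic population grid
#'
#' Population is a sum of Gaussian settlement kernels: settlement k
#' contributes `peak_density * size_mult_k * exp(-d^2 / (2 sd^2))`
#' persons/km^2 at distance `d` from its core, discretized to persons per
#' cell. Cells far from all settlements are empty; values are continuous
#' non-negative person counts, as in gridded population products.
#'
#' @param spec a [landscape_spec()].
#' @param dem elevation grid (used to place settlements when
#'   `settlements` is not supplied).
#' @param settlements optional data.frame from [make_settlements()].
#' @return population grid (persons per cell); attribute `total` holds
#'   the grid total.
#' @export
make_population <- function(spec, dem, settlements = NULL) {
  if (is.null(settlements)) settlements <- make_settlements(spec, dem)
  nr <- spec$rows; nc <- spec$cols; cs <- spec$cell_size
  pop <- matrix(0, nr, nc)
  if (nrow(settlements)) {
    cx <- dem$xll + (seq_len(nc) - 0.5) * cs
    cy <- dem$yll + (nr - seq_len(nr) + 0.5) * cs
    X <- matrix(cx, nr, nc, byrow = TRUE)
    Y <- matrix(cy, nr, nc)
    area <- (cs / 1000)^2
    s2 <- spec$settlement_kernel_sd_m^2
    for (k in seq_len(nrow(settlements))) {
      d2 <- (X - settlements$x[k])^2 + (Y - settlements$y[k])^2
      pop <- pop + spec$settlement_peak_density * settlements$size_mult[k] *
        exp(-d2 / (2 * s2)) * area
    }
  }
  g <- grid_new(pop, dem$xll, dem$yll, cs)
  attr(g, "total") <- sum(pop)
  g
}

#' Road network over the settlements
#'
#' The minimum spanning tree of the settlement cores under Euclidean edge
#' weights, drawn as straight polylines — the simplest connected network
#' that exercises road-speed overrides in the friction model.
#'
#' @param spec a [landscape_spec()].
#' @param settlements data.frame from [make_settlements()].
#' @return polyline vector layer with a `road_id` attribute.
#' @export
make_roads <- function(spec, settlements) {
  n <- nrow(settlements)
  d <- as.matrix(stats::dist(settlements[, c("x", "y")]))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  el <- igraph::as_edgelist(mst, names = FALSE)
  geoms <- lapply(seq_len(nrow(el)), function(i) {
    a <- el[i, 1]; b <- el[i, 2]
    list(type = "linestring",
         coords = rbind(c(settlements$x[a], settlements$y[a]),
                        c(settlements$x[b], settlements$y[b])))
  })
  vector_layer(geoms, data.frame(road_id = seq_len(nrow(el))))
}

# Voronoi tessellation of the extent around settlement cores.
voronoi_polygons <- function(spec, settlements) {
  xmax <- spec$cols * spec$cell_size
  ymax <- spec$rows * spec$cell_size
  dd <- deldir::deldir(settlements$x, settlements$y, rw = c(0, xmax, 0, ymax),
                       suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  geoms <- vector("list", nrow(settlements))
  for (t in tiles) {
    geoms[[t$ptNum]] <- list(type = "polygon", coords = cbind(t$x, t$y))
  }
  if (any(vapply(geoms, is.null, logical(1))))
    stop("Voronoi tessellation dropped a settlement (coincident points?)")
  geoms
}

#' Administrative units, facilities and volunteer roster
#'
#' Fokontany are the Voronoi cells of the settlement cores clipped to the
#' extent; communes are k-means clusters of settlements and districts a
#' west/east split of communes. A subset of settlements hosts a CSB, a
#' subset hosts a PA; each facility sits on the highest-population cell of
#' its host fokontany. One CSB (the one with the least-populated host) is
#' given no volunteers, making it ineligible for reassignment. Every
#' fokontany draws its AC count from `acs_probs` and is assigned its
#' closest eligible CSB with probability `1 - misassign_csb` (else a
#' random other eligible CSB), and likewise for PAs; fokontany in communes
#' without a PA get no PA assignment. Closeness uses fokontany-mean travel
#' time when `tt_csb` / `tt_pa` matrices are supplied (as the full
#' pipeline does), else straight-line distance from the settlement core.
#'
#' @param spec a [landscape_spec()].
#' @param population population grid from [make_population()].
#' @param settlements optional settlements data.frame; derived from
#'   population peaks when absent.
#' @param tt_csb,tt_pa optional fokontany x facility travel-time matrices
#'   from [travel_time_matrix()].
#' @return list with `fokontany` (polygon layer: `fokontany_id`,
#'   `commune_id`, `district_id`), `roster` (data.frame), `facilities`
#'   (data.frame: `facility_id`, `kind`, `x`, `y`, `row`, `col`,
#'   `host_fokontany`, `eligible`).
#' @export
make_admin_and_roster <- function(spec, population, settlements = NULL,
                                  tt_csb = NULL, tt_pa = NULL) {
  if (is.null(settlements)) settlements <- find_population_peaks(spec, population)
  n <- nrow(settlements)
  if (n < max(spec$n_csb, spec$n_pa))
    stop("fewer settlements than requested facilities")
  geoms <- voronoi_polygons(spec, settlements)
  fok_ids <- sprintf("FK%02d", seq_len(n))

  # communes: k-means clusters of cores, labelled west to east
  # (k-means needs strictly fewer centers than points)
  k_comm <- max(1L, min(spec$n_communes, n - 1L))
  km <- with_seed(spec$seed + 53L,
                  stats::kmeans(settlements[, c("x", "y")],
                                centers = k_comm, nstart = 5))
  lab <- rank(km$centers[, 1], ties.method = "first")
  commune <- sprintf("CM%02d", lab[km$cluster])
  cx_order <- order(km$centers[, 1])
  west <- sprintf("CM%02d", lab[cx_order[seq_len(ceiling(length(cx_order) / 2))]])
  district <- ifelse(commune %in% west, "District-West", "District-East")

  fokontany <- vector_layer(
    geoms,
    data.frame(fokontany_id = fok_ids, commune_id = commune,
               district_id = district,
               settlement_row = settlements$row,
               settlement_col = settlements$col,
               stringsAsFactors = FALSE))

  zones <- zone_raster(fokontany, population)
  # CSB hosts are free draws; PA hosts are spread one per commune (supply
  # points serve communes), so only communes left over lack a PA
  hosts <- with_seed(spec$seed + 67L, {
    csb <- sort(sample.int(n, spec$n_csb))
    comms <- sort(unique(commune))
    k <- min(spec$n_pa, length(comms))
    pa_comms <- if (length(comms) == 1L) comms else sample(comms, k)
    pa <- vapply(pa_comms, function(cm) {
      inside <- which(commune == cm)
      if (length(inside) == 1L) inside else sample(inside, 1)
    }, integer(1))
    extra <- spec$n_pa - length(pa)
    if (extra > 0) {
      pool <- setdiff(seq_len(n), pa)
      pa <- c(pa, if (length(pool) == 1L) pool else sample(pool, extra))
    }
    list(csb = csb, pa = sort(unname(pa)))
  })
  place <- function(k) {
    cells <- which(zones == k)
    best <- cells[which.max(population$values[cells])]
    nr <- nrow(population$values)
    r <- ((best - 1L) %% nr) + 1L
    c <- ((best - 1L) %/% nr) + 1L
    c(r, c)
  }
  fac_row <- function(idx, kind, tag) {
    rc <- t(vapply(idx, place, integer(2)))
    data.frame(facility_id = sprintf("%s%02d", tag, seq_along(idx)),
               kind = kind,
               x = population$xll + (rc[, 2] - 0.5) * spec$cell_size,
               y = population$yll + (spec$rows - rc[, 1] + 0.5) * spec$cell_size,
               row = rc[, 1], col = rc[, 2],
               host_fokontany = fok_ids[idx],
               host_settlement = idx,
               eligible = TRUE, stringsAsFactors = FALSE)
  }
  facilities <- rbind(fac_row(hosts$csb, "CSB", "CSB"),
                      fac_row(hosts$pa, "PA", "PA"))

  # one CSB supports no volunteers (ineligible for reassignment)
  csb <- facilities[facilities$kind == "CSB", ]
  if (nrow(csb) >= 3) {
    host_pop <- vapply(csb$host_settlement, function(k)
      sum(population$values[which(zones == k)]), numeric(1))
    drop_id <- csb$facility_id[order(host_pop, csb$facility_id)[1]]
    facilities$eligible[facilities$facility_id == drop_id] <- FALSE
  }

  elig_csb <- facilities$facility_id[facilities$kind == "CSB" & facilities$eligible]
  all_pa <- facilities$facility_id[facilities$kind == "PA"]
  pa_communes <- unique(commune[facilities$host_settlement[facilities$kind == "PA"]])

  # closeness: travel-time matrix if available, else Euclidean from core
  prox <- function(ids, tt) {
    sub_fac <- facilities[match(ids, facilities$facility_id), ]
    if (!is.null(tt)) {
      tt[fok_ids, ids, drop = FALSE]
    } else {
      outer(seq_len(n), seq_len(nrow(sub_fac)), function(i, j)
        sqrt((settlements$x[i] - sub_fac$x[j])^2 +
             (settlements$y[i] - sub_fac$y[j])^2))
    }
  }
  assign_one <- function(ids, tt, p_mis) {
    m <- prox(ids, tt)
    colnames(m) <- ids
    vapply(seq_len(n), function(i) {
      o <- order(m[i, ], ids)   # deterministic tie-break by id
      closest <- ids[o[1]]
      if (length(ids) > 1 && stats::runif(1) < p_mis)
        sample(setdiff(ids, closest), 1)
      else closest
    }, character(1))
  }
  with_seed(spec$seed + 97L, {
    n_acs <- sample(as.integer(names(spec$acs_probs)), n, TRUE,
                    prob = spec$acs_probs)
    assigned_csb <- assign_one(elig_csb, tt_csb, spec$misassign_csb)
    assigned_pa <- assign_one(all_pa, tt_pa, spec$misassign_pa)
  })
  assigned_pa[!(commune %in% pa_communes)] <- NA_character_

  roster <- data.frame(fokontany_id = fok_ids, n_acs = n_acs,
                       assigned_csb_id = assigned_csb,
                       assigned_pa_id = assigned_pa,
                       commune_id = commune, district_id = district,
                       stringsAsFactors = FALSE)
  list(fokontany = fokontany, roster = roster, facilities = facilities)
}

# Settlement cores recovered as separated local maxima of the population
# surface (used when make_admin_and_roster is called without settlements).
find_population_peaks <- function(spec, population) {
  v <- population$values
  nr <- nrow(v); nc <- ncol(v)
  ord <- order(v, decreasing = TRUE)
  rows <- integer(0); cols <- integer(0)
  for (i in ord) {
    r <- ((i - 1L) %% nr) + 1L
    c <- ((i - 1L) %/% nr) + 1L
    if (length(rows) &&
        any(pmax(abs(rows - r), abs(cols - c)) < spec$min_separation_cells))
      next
    rows <- c(rows, r); cols <- c(cols, c)
    if (length(rows) == spec$n_settlements) break
  }
  if (length(rows) < spec$n_settlements)
    stop("could not recover ", spec$n_settlements, " population peaks")
  data.frame(settlement_id = seq_along(rows), row = rows, col = cols,
             x = population$xll + (cols - 0.5) * population$cell_size,
             y = population$yll + (nr - rows + 0.5) * population$cell_size,
             size_mult = NA_real_)
}

#' Generate a complete synthetic landscape and run the spatial stack
#'
#' Orchestrates the full input stack and the derived layers: terrain,
#' land cover, settlements, population, roads, rivers, slope, friction,
#' habitable mask, per-facility travel-time fields, fokontany/commune
#' tessellation and the volunteer roster (assigned by travel-time
#' closeness with the configured misassignment probabilities).
#'
#' @param spec a [landscape_spec()].
#' @param table walking-speed table (default [speed_table()]).
#' @return object of class `chw_landscape`: list with all layers and
#'   tables.
#' @export
simulate_landscape <- function(spec, table = speed_table()) {
  dem <- make_dem(spec)
  landcover <- make_landcover(spec)
  settlements <- make_settlements(spec, dem)
  population <- make_population(spec, dem, settlements)
  roads_layer <- make_roads(spec, settlements)
  roads <- rasterize(roads_layer, dem)
  rivers <- river_grid(dem, spec$stream_threshold)
  slope <- slope_grid(dem)
  friction <- build_friction(landcover, roads, slope, rivers, table)
  mask <- habitable_mask(population)

  adm0 <- make_admin_and_roster(spec, population, settlements)
  zones <- zone_raster(adm0$fokontany, dem)
  fields <- facility_fields(friction, adm0$facilities)
  csb_ids <- adm0$facilities$facility_id[adm0$facilities$kind == "CSB"]
  pa_ids <- adm0$facilities$facility_id[adm0$facilities$kind == "PA"]
  tt_csb <- travel_time_matrix(fields[csb_ids], mask, adm0$fokontany, zones)
  tt_pa <- travel_time_matrix(fields[pa_ids], mask, adm0$fokontany, zones)
  adm <- make_admin_and_roster(spec, population, settlements,
                               tt_csb = tt_csb, tt_pa = tt_pa)

  structure(list(
    spec = spec, speed_table = table,
    dem = dem, landcover = landcover, population = population,
    settlements = settlements, roads_layer = roads_layer, roads = roads,
    rivers = rivers, slope = slope, friction = friction, mask = mask,
    fokontany = adm$fokontany, roster = adm$roster,
    facilities = adm$facilities, zones = zones, fields = fields,
    tt_csb = tt_csb, tt_pa = tt_pa
  ), class = "chw_landscape")
}

#' @export
print.chw_landscape <- function(x, ...) {
  cat(sprintf("<chw_landscape> %dx%d @ %gm (seed %d): %d fokontany, %d CSB, %d PA, %.0f people\n",
              x$spec$rows, x$spec$cols, x$spec$cell_size, x$spec$seed,
              nrow(x$roster), sum(x$facilities$kind == "CSB"),
              sum(x$facilities$kind == "PA"), sum(x$population$values)))
  invisible(x)
}

#' Write the landscape's input stack to a directory
#'
#' Rasters go out as ESRI ASCII grids, vector layers as GeoJSON, tables as
#' CSV — the formats the rest of the pipeline reads back.
#'
#' @param land a `chw_landscape`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_landscape <- function(land, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grid(land$dem, file.path(dir, "dem.asc"))
  write_grid(land$landcover, file.path(dir, "landcover.asc"))
  write_grid(land$population, file.path(dir, "population.asc"))
  write_grid(land$friction, file.path(dir, "friction.asc"))
  write_geojson(land$fokontany, file.path(dir, "fokontany.geojson"))
  write_geojson(land$roads_layer, file.path(dir, "roads.geojson"))
  fac_pts <- vector_layer(
    lapply(seq_len(nrow(land$facilities)), function(i)
      list(type = "point",
           coords = matrix(c(land$facilities$x[i], land$facilities$y[i]), 1))),
    land$facilities)
  write_geojson(fac_pts, file.path(dir, "facilities.geojson"))
  utils::write.csv(land$roster, file.path(dir, "roster.csv"),
                   row.names = FALSE)
  utils::write.csv(land$facilities, file.path(dir, "facilities.csv"),
                   row.names = FALSE)
  utils::write.csv(land$settlements, file.path(dir, "settlements.csv"),
                   row.names = FALSE)
  invisible(dir)
}
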