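test_that("the generator is fully deterministic under a fixed seed", {
  s <- small_spec(seed = 42)
  a <- simulate_landscape(s)
  b <- simulate_landscape(s)
  expect_identical(a$dem$values, b$dem$values)
  expect_identical(a$landcover$values, b$landcover$values)
  expect_identical(a$population$values, b$population$values)
  expect_identical(a$friction$values, b$friction$values)
  expect_identical(a$roster, b$roster)
  expect_identical(a$facilities, b$facilities)
  expect_identical(a$tt_csb, b$tt_csb)
  # a different seed changes the terrain but keeps structural invariants
  c <- simulate_landscape(small_spec(seed = 43))
  expect_false(identical(a$dem$values, c$dem$values))
  expect_equal(nrow(c$roster), 12)
})

test_that("zero roughness gives the planar trend with parallel southward flow", {
  s <- landscape_spec(rows = 20, cols = 20, seed = 3, relief_amplitude_m = 0,
                      n_settlements = 4, min_separation_cells = 3)
  dem <- make_dem(s)
  ry <- (seq_len(20) - 1) / 19
  expect_equal(dem$values, matrix(150 * (1 - ry), 20, 20), tolerance = 1e-3)
  dir <- d8_flow_direction(dem)
  expect_true(all(dir$values[-20, ] == 5))  # everything points S
})

test_that("every cell of a generated DEM has a descending D8 path to the border", {
  s <- small_spec(seed = 5)
  dem <- make_dem(s)
  dir <- d8_flow_direction(dem)
  d <- dir$values; z <- dem$values
  nr <- nrow(d); nc <- ncol(d)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1); dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  # walk from a grid of probe cells; strict descent, bounded steps
  for (r0 in seq(2, nr - 1, by = 7)) for (c0 in seq(2, nc - 1, by = 7)) {
    r <- r0; c <- c0; steps <- 0
    repeat {
      k <- d[r, c]
      if (k == 0) break
      r2 <- r + dr[k]; c2 <- c + dc[k]
      expect_lt(z[r2, c2], z[r, c])
      r <- r2; c <- c2
      steps <- steps + 1
      expect_lt(steps, nr * nc)
    }
    expect_true(r == 1 || r == nr || c == 1 || c == nc)
  }
})

test_that("a single settlement kernel integrates to its analytic mass", {
  s <- landscape_spec(rows = 60, cols = 60, seed = 9, n_settlements = 2,
                      settlement_size_sdlog = 0)
  dem <- make_dem(s)
  settle <- data.frame(settlement_id = 1, row = 30, col = 30,
                       x = 2950, y = 3050, size_mult = 1)
  pop <- make_population(s, dem, settle)
  sd_km <- s$settlement_kernel_sd_m / 1000
  analytic <- s$settlement_peak_density * 2 * pi * sd_km^2
  expect_equal(sum(pop$values), analytic, tolerance = 0.01)
  # zero settlements: empty grid
  pop0 <- make_population(s, dem, settle[0, ])
  expect_true(all(pop0$values == 0))
})

test_that("the habitable threshold captures at least 90% of the population", {
  for (seed in c(1, 2)) {
    s <- small_spec(seed = seed)
    dem <- make_dem(s)
    pop <- make_population(s, dem)
    mask <- habitable_mask(pop, 10)
    share <- sum(pop$values[mask$values > 0]) / sum(pop$values)
    expect_gte(share, 0.9)
  }
})

test_that("fokontany polygons partition the extent", {
  s <- small_spec(seed = 11)
  land <- simulate_landscape(s)
  areas <- layer_areas_km2(land$fokontany)
  extent_km2 <- (s$rows * s$cell_size / 1000) * (s$cols * s$cell_size / 1000)
  expect_equal(sum(areas), extent_km2, tolerance = 1e-9)
  # every cell center belongs to exactly one fokontany
  expect_false(any(is.na(land$zones)))
  # every fokontany has at least one habitable cell
  tab <- table(factor(land$zones[land$mask$values > 0], levels = seq_len(12)))
  expect_true(all(tab >= 1))
})

test_that("four settlements on a square give four congruent fokontany", {
  s <- landscape_spec(rows = 40, cols = 40, seed = 2, n_settlements = 4,
                      relief_amplitude_m = 0, min_separation_cells = 3)
  dem <- make_dem(s)
  settle <- data.frame(settlement_id = 1:4,
                       row = c(10, 10, 31, 31), col = c(10, 31, 10, 31),
                       x = c(950, 3050, 950, 3050),
                       y = c(3050, 3050, 950, 950),
                       size_mult = 1)
  pop <- make_population(s, dem, settle)
  adm <- make_admin_and_roster(s, pop, settle)
  areas <- layer_areas_km2(adm$fokontany)
  expect_equal(areas, rep(4, 4), tolerance = 1e-9)  # 2 km x 2 km each
})

test_that("the AC-count distribution concentrates on two volunteers", {
  counts <- unlist(lapply(1:5, function(seed) {
    s <- small_spec(seed = seed)
    dem <- make_dem(s)
    pop <- make_population(s, dem)
    make_admin_and_roster(s, pop)$roster$n_acs
  }))
  expect_gte(mean(counts == 2), 0.8)
  expect_true(all(counts >= 1 & counts <= 6))
})

test_that("zero misassignment makes every assignment the travel-time-closest facility", {
  s <- small_spec(seed = 21, misassign_csb = 0, misassign_pa = 0)
  land <- simulate_landscape(s)
  sc <- scenario_table(land$roster, land$tt_csb, "CSB")
  expect_true(all(!sc$misassigned))
  expect_equal(sc$assigned_minutes, sc$closest_minutes)
  sp <- scenario_table(land$roster, land$tt_pa, "PA")
  expect_true(all(!sp$misassigned[!sp$excluded]))
})

test_that("the written landscape stack reads back consistently", {
  s <- small_spec(seed = 31)
  land <- simulate_landscape(s)
  dir <- withr::local_tempdir()
  write_landscape(land, dir)
  dem2 <- read_grid(file.path(dir, "dem.asc"), expected_cell_size = 100)
  expect_equal(dem2$values, land$dem$values, tolerance = 1e-12)
  fok2 <- read_geojson(file.path(dir, "fokontany.geojson"))
  expect_equal(fok2$attrs$fokontany_id, land$fokontany$attrs$fokontany_id)
  expect_equal(layer_areas_km2(fok2), layer_areas_km2(land$fokontany),
               tolerance = 1e-6)
  roster2 <- utils::read.csv(file.path(dir, "roster.csv"),
                             stringsAsFactors = FALSE)
  expect_equal(roster2$n_acs, land$roster$n_acs)
})
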