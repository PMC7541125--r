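test_that("ASCII grid round-trip preserves values, transform and nodata", {
  m <- matrix(c(1.5, 2, NA, 4, 5.25, 6, 7, 8, 9.125, 10, 11, 12,
                13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25),
              5, 5)
  g <- grid_new(m, xll = 1000, yll = 2000, cell_size = 100, nodata = -1)
  f <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, f)
  g2 <- read_grid(f, expected_cell_size = 100)
  expect_identical(dim(g2), c(5L, 5L))
  expect_equal(g2$values, g$values)
  expect_equal(g2$xll, 1000)
  expect_equal(g2$yll, 2000)
  expect_equal(g2$cell_size, 100)
  expect_equal(g2$nodata, -1)
  # second round trip is bit-identical
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_grid(g2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("read_grid enforces its contract", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 50", "nodata_value -9999",
               "1 2", "3 4"), f)
  expect_error(read_grid(f, expected_cell_size = 100), "does not match")
  expect_error(read_grid("no/such/file.asc"), "no such file")
  # dx/dy extension encodes a non-square transform: rejected
  fbad <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "dx 50", "dy 100", "nodata_value -9999", "1 2", "3 4"), fbad)
  expect_error(read_grid(fbad), "non-square|non-north-up")
  ftrunc <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 50", "1 2 3"), ftrunc)
  expect_error(read_grid(ftrunc), "expected 4")
})

test_that("nearest-neighbour alignment replicates coarse cells in blocks", {
  coarse <- grid_new(matrix(1:4, 2, 2), 0, 0, 300)  # 600 x 600 m extent
  ref <- grid_new(matrix(0, 6, 6), 0, 0, 100)
  out <- align_stack(list(coarse), ref, "nearest")[[1]]
  expect_identical(dim(out), c(6L, 6L))
  for (r in 1:6) for (c in 1:6)
    expect_equal(out$values[r, c],
                 coarse$values[ceiling(r / 3), ceiling(c / 3)])
})

test_that("alignment preserves constants and planes, and is idempotent", {
  ref <- grid_new(matrix(0, 10, 10), 0, 0, 100)
  const <- grid_new(matrix(7, 40, 40), 0, 0, 30)
  out <- resample_to(const, ref, "bilinear")
  expect_true(all(out$values == 7))
  # plane z = x sampled on a 30 m grid, bilinear onto 100 m: exact
  fine <- grid_new(matrix(0, 40, 40), 0, 0, 30)
  ctr <- cell_centers(fine)
  fine$values <- matrix(rep(ctr$x, each = 40), 40, 40)
  out <- resample_to(fine, ref, "bilinear")
  ctr_ref <- cell_centers(ref)
  interior <- 2:9
  for (r in interior)
    expect_equal(out$values[r, interior], ctr_ref$x[interior], tolerance = 1e-12)
  # aligning an aligned grid is a no-op
  g <- grid_new(matrix(rnorm(100), 10, 10), 0, 0, 100)
  expect_identical(align_stack(list(g), ref)[[1]]$values, g$values)
  # disjoint extents error
  far <- grid_new(matrix(1, 5, 5), 1e6, 1e6, 100)
  expect_error(resample_to(far, ref), "disjoint")
})

test_that("rasterize burns lines, polygons and points as specified", {
  ref <- grid_new(matrix(0, 5, 5), 0, 0, 100)
  # horizontal polyline through the center of row 2 (y = 350)
  line <- vector_layer(list(list(type = "linestring",
                                 coords = rbind(c(0, 350), c(500, 350)))))
  out <- rasterize(line, ref)
  expect_true(all(out$values[2, ] == 1))
  expect_true(all(is.na(out$values[-2, ])))
  # polygon covering the whole extent
  poly <- vector_layer(list(list(type = "polygon",
                                 coords = rbind(c(-10, -10), c(510, -10),
                                                c(510, 510), c(-10, 510)))))
  expect_true(all(rasterize(poly, ref)$values == 1))
  # point burns its containing cell
  pt <- vector_layer(list(list(type = "point", coords = matrix(c(250, 450), 1))),
                     data.frame(v = 9))
  outp <- rasterize(pt, ref, burn_value_field = "v")
  expect_equal(outp$values[1, 3], 9)
  expect_equal(sum(!is.na(outp$values)), 1L)
  expect_warning(out_empty <- rasterize(vector_layer(list()), ref), "empty")
  expect_true(all(is.na(out_empty$values)))
})

test_that("crossing roads burn exactly the cells within half a cell of either line", {
  ref <- grid_new(matrix(0, 9, 9), 0, 0, 100)
  roads <- vector_layer(list(
    list(type = "linestring", coords = rbind(c(50, 50), c(850, 850))),
    list(type = "linestring", coords = rbind(c(50, 450), c(850, 350)))
  ))
  out <- rasterize(roads, ref)
  ctr <- cell_centers(ref)
  seg_dist <- function(px, py, a, b) {  # independent point-to-segment distance
    ab <- b - a
    t <- min(max(sum((c(px, py) - a) * ab) / sum(ab * ab), 0), 1)
    q <- a + t * ab
    sqrt(sum((c(px, py) - q)^2))
  }
  for (r in 1:9) for (c in 1:9) {
    d <- min(seg_dist(ctr$x[c], ctr$y[r], c(50, 50), c(850, 850)),
             seg_dist(ctr$x[c], ctr$y[r], c(50, 450), c(850, 350)))
    expect_equal(!is.na(out$values[r, c]), d <= 50 + 1e-9,
                 info = sprintf("cell (%d,%d), dist %.2f", r, c, d))
  }
  # every point along each line is within half a cell diagonal of a burned
  # cell center (no gaps in the burned road)
  burned <- which(!is.na(out$values), arr.ind = TRUE)
  bx <- ctr$x[burned[, 2]]; by <- ctr$y[burned[, 1]]
  for (t in seq(0, 1, by = 0.02)) {
    px <- 50 + t * 800; py <- 50 + t * 800
    expect_lte(min(sqrt((bx - px)^2 + (by - py)^2)), 100 * sqrt(2) / 2 + 1e-9)
  }
})

test_that("GeoJSON round-trip preserves geometry and attributes", {
  layer <- vector_layer(
    list(list(type = "point", coords = matrix(c(10.5, 20.25), 1)),
         list(type = "linestring", coords = rbind(c(0, 0), c(100, 50), c(200, 0))),
         list(type = "polygon", coords = rbind(c(0, 0), c(100, 0), c(50, 80)))),
    data.frame(name = c("a", "b", "c"), v = c(1.5, 2, 3),
               stringsAsFactors = FALSE),
    crs_id = "epsg:29738")
  f <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(layer, f)
  back <- read_geojson(f)
  expect_equal(back$crs_id, "epsg:29738")
  expect_equal(vapply(back$geoms, `[[`, "", "type"),
               c("point", "linestring", "polygon"))
  for (k in 1:3)
    expect_equal(back$geoms[[k]]$coords, layer$geoms[[k]]$coords,
                 ignore_attr = TRUE)
  expect_equal(back$attrs$name, layer$attrs$name)
  expect_equal(back$attrs$v, layer$attrs$v)
})
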