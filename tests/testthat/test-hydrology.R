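plane_east_up <- function(n = 8, cs = 100) {
  # z = x: steepest descent is due west
  g <- grid_new(matrix(0, n, n), 0, 0, cs)
  ctr <- cell_centers(g)
  g$values <- matrix(rep(ctr$x * 0.01, each = n), n, n)
  g
}

test_that("D8 directions on a tilted plane all point west", {
  dir <- d8_flow_direction(plane_east_up())
  expect_true(all(dir$values[, -1] == 7))  # 7 = W
  expect_true(all(dir$values[, 1] == 0))   # western border drains off-grid
})

test_that("a cardinal neighbour beats a diagonal one on equal drop", {
  # center 10; S neighbour 8 and SE neighbour 8: same drop, S is nearer
  z <- matrix(10, 3, 3)
  z[3, 2] <- 8; z[3, 3] <- 8
  dir <- d8_flow_direction(grid_new(z, 0, 0, 100))
  expect_equal(dir$values[2, 2], 5)  # S
})

test_that("interior cells without a downslope neighbour are rejected", {
  z <- matrix(10, 5, 5)
  z[3, 3] <- 1  # a pit
  expect_error(d8_flow_direction(grid_new(z, 0, 0, 100)), "fill_depressions")
  filled <- fill_depressions(grid_new(z, 0, 0, 100))
  expect_silent(d8_flow_direction(filled))
})

test_that("flow accumulation counts upslope cells on a draining plane", {
  dir <- d8_flow_direction(plane_east_up(6))
  acc <- flow_accumulation(dir)
  # column j (1 = west edge) collects everything to its east: n - j + 1
  for (j in 1:6) expect_true(all(acc$values[, j] == 6 - j + 1))
})

test_that("a convergent bowl accumulates every cell at its outlet", {
  n <- 9
  g <- grid_new(matrix(0, n, n), 0, 0, 100)
  # cone centred on the SE corner cell, tilted so all paths reach it
  for (r in 1:n) for (c in 1:n)
    g$values[r, c] <- sqrt((n - r)^2 + (n - c)^2)
  dir <- d8_flow_direction(g)
  acc <- flow_accumulation(dir)
  expect_equal(acc$values[n, n], n * n)
})

test_that("accumulation matches the brute-force path-walk oracle on random DEMs", {
  for (seed in 1:8) {
    set.seed(seed)
    nr <- sample(6:15, 1); nc <- sample(6:15, 1)
    dem <- fill_depressions(grid_new(matrix(rnorm(nr * nc, 0, 5), nr, nc),
                                     0, 0, 100))
    dir <- d8_flow_direction(dem)
    acc <- flow_accumulation(dir)
    expect_equal(acc$values, oracle_accumulation(dir))
    expect_true(all(acc$values >= 1))
    # conservation: outlet accumulations sum to the number of cells
    outlets <- dir$values == 0
    expect_equal(sum(acc$values[outlets]), nr * nc)
    # each cell equals 1 + sum of inflowing neighbours' accumulations
    recv <- chwaccess:::d8_receivers(dir)
    inflow <- tapply(acc$values[!is.na(recv)], recv[!is.na(recv)], sum)
    expected <- rep(1, nr * nc)
    expected[as.integer(names(inflow))] <- 1 + inflow
    expect_equal(as.vector(acc$values), expected, ignore_attr = TRUE)
  }
})

test_that("a cyclic direction grid is rejected", {
  d <- matrix(0, 3, 3)
  d[2, 2] <- 3  # points E
  d[2, 3] <- 7  # points W, back again
  expect_error(flow_accumulation(grid_new(d, 0, 0, 100)), "cycle")
})

test_that("Strahler order follows the junction rules", {
  # two order-1 tributaries joining give order 2; adding an order-1 to an
  # order-2 keeps order 2
  dir <- build_binary_tree_dirs(2)
  acc <- flow_accumulation(dir)
  str <- strahler_order(dir, acc, stream_threshold = 1)
  nr <- nrow(dir$values)
  root <- c(nr - 1L, (ncol(dir$values) + 1L) %/% 2L)
  expect_equal(str$values[root[1], root[2]], 3)  # depth-2 tree: order 3
  # junction one level up has two order-1 inflows: order 2
  expect_equal(str$values[root[1] - 2L, root[2] - 2L], 2)
  # side-tributary case: grow an order-1 chain into an order-2 reach
  d <- matrix(0, 5, 5)
  d[1, 2] <- 5; d[2, 2] <- 5; d[1, 3] <- 6; d[2, 3] <- 6  # two chains meet
  d[3, 2] <- 5; d[4, 2] <- 5                               # main stem down
  d[3, 1] <- 3                                             # order-1 side inflow
  g <- grid_new(d, 0, 0, 100)
  a <- flow_accumulation(g)
  s <- strahler_order(g, a, stream_threshold = 1)
  expect_equal(s$values[3, 2], 2)  # after the junction of two order-1s
  expect_equal(s$values[4, 2], 2)  # order-1 side inflow does not raise it
})

test_that("symmetric binary drainage trees of depth k reach order k + 1", {
  for (k in 1:4) {
    dir <- build_binary_tree_dirs(k)
    acc <- flow_accumulation(dir)
    str <- strahler_order(dir, acc, stream_threshold = 1)
    nr <- nrow(dir$values)
    root <- c(nr - 1L, (ncol(dir$values) + 1L) %/% 2L)
    expect_equal(str$values[root[1], root[2]], k + 1)
    # recursive oracle agrees everywhere on the stream network
    oracle <- oracle_strahler(dir, rep(TRUE, length(dir$values)))
    tree <- dir$values > 0 | acc$values > 1
    expect_equal(str$values[tree], oracle[tree] + 0)
  }
})

test_that("width classes map orders through the configured breaks", {
  s <- grid_new(matrix(c(0, 1, 3, 4, 5, 6, 9, 0, 2), 3, 3), 0, 0, 100)
  w <- width_class(s)
  expect_equal(w$values,
               matrix(c(0, 1, 1, 2, 2, 3, 3, 0, 1), 3, 3))
  # width class never decreases downstream along a flow path
  spec <- small_spec(seed = 8)
  dem <- make_dem(spec)
  riv <- river_grid(dem, stream_threshold = 30)
  recv <- chwaccess:::d8_receivers(riv$direction)
  wv <- as.vector(riv$width_class$values)
  sv <- as.vector(riv$strahler$values)
  on_stream <- which(sv > 0 & !is.na(recv))
  downstream_stream <- on_stream[sv[recv[on_stream]] > 0]
  expect_true(all(wv[recv[downstream_stream]] >= wv[downstream_stream]))
  # and the whole stack is deterministic
  riv2 <- river_grid(dem, stream_threshold = 30)
  expect_identical(riv$strahler$values, riv2$strahler$values)
})
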