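# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: graph shortest paths go through igraph on an
# explicitly built edge list, point-in-polygon is a hand-written ray
# casting, accumulation walks every flow path one by one.

# Explicit-graph Dijkstra oracle for grid cost distance.
# friction: matrix of minutes per cell (Inf/NA impassable).
# sources: matrix of (row, col). Returns matrix of minutes.
oracle_cost_distance <- function(friction, sources) {
  nr <- nrow(friction); nc <- ncol(friction); n <- nr * nc
  id <- function(r, c) (c - 1L) * nr + r
  pass <- is.finite(friction)
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))
  parts <- lapply(offs, function(o) {
    d <- if (all(o != 0)) sqrt(2) else 1
    rs <- max(1, 1 - o[1]):min(nr, nr - o[1])
    cs <- max(1, 1 - o[2]):min(nc, nc - o[2])
    rc <- expand.grid(r = rs, c = cs)
    i <- id(rc$r, rc$c)
    j <- id(rc$r + o[1], rc$c + o[2])
    keep <- pass[i] & pass[j]
    list(from = i[keep], to = j[keep],
         w = 0.5 * (friction[i[keep]] + friction[j[keep]]) * d)
  })
  from <- unlist(lapply(parts, `[[`, "from"))
  to <- unlist(lapply(parts, `[[`, "to"))
  w <- unlist(lapply(parts, `[[`, "w"))
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  src <- id(sources[, 1], sources[, 2])
  dm <- igraph::distances(g, v = src, weights = w)
  res <- apply(dm, 2, min)
  res[!pass] <- NA_real_
  matrix(res, nr, nc)
}

# Ray-casting point-in-polygon (even-odd rule), one point at a time.
oracle_point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  for (p in seq_along(px)) {
    x <- px[p]; y <- py[p]; cross <- 0L
    for (i in seq_len(n)) {
      j <- if (i == 1L) n else i - 1L
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      if ((yi > y) != (yj > y)) {
        xint <- xi + (y - yi) / (yj - yi) * (xj - xi)
        if (x < xint) cross <- cross + 1L
      }
    }
    inside[p] <- (cross %% 2L) == 1L
  }
  inside
}

# Brute-force flow accumulation: walk the flow path from every cell and
# count visits.
oracle_accumulation <- function(direction_grid) {
  d <- direction_grid$values
  nr <- nrow(d); nc <- ncol(d); n <- nr * nc
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  acc <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    cr <- r; cc <- c
    repeat {
      acc[cr, cc] <- acc[cr, cc] + 1
      k <- d[cr, cc]
      if (k == 0) break
      cr2 <- cr + dr[k]; cc2 <- cc + dc[k]
      if (cr2 < 1 || cr2 > nr || cc2 < 1 || cc2 > nc) break
      cr <- cr2; cc <- cc2
    }
  }
  acc
}

# Recursive Strahler-order oracle on the flow forest.
oracle_strahler <- function(direction_grid, stream) {
  d <- direction_grid$values
  nr <- nrow(d); nc <- ncol(d); n <- nr * nc
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  recv <- rep(NA_integer_, n)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- d[r, c]
    if (k > 0) {
      r2 <- r + dr[k]; c2 <- c + dc[k]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc)
        recv[(c - 1L) * nr + r] <- (c2 - 1L) * nr + r2
    }
  }
  children <- vector("list", n)
  for (i in seq_len(n)) {
    j <- recv[i]
    if (!is.na(j)) children[[j]] <- c(children[[j]], i)
  }
  memo <- rep(NA_integer_, n)
  rec <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    kid <- children[[i]]
    kid <- kid[stream[kid]]
    o <- if (!length(kid)) 1L else {
      os <- vapply(kid, rec, integer(1))
      mx <- max(os)
      mx + as.integer(sum(os == mx) >= 2L)
    }
    memo[i] <<- o
    o
  }
  out <- rep(0L, n)
  for (i in which(stream)) out[i] <- rec(i)
  matrix(out, nr, nc)
}

# Symmetric binary drainage tree of the given depth as a D8 direction
# grid: leaves have order 1; the outlet should come out at depth + 1.
build_binary_tree_dirs <- function(depth) {
  ext <- 2^depth - 1
  nr <- ext + 2L
  nc <- 2L * ext + 3L
  dir <- matrix(0, nr, nc)
  place <- function(r, c, d) {
    if (d == 0) return()
    L <- 2^(d - 1)
    for (t in seq_len(L)) {
      dir[r - t, c - t] <<- 4  # SE toward the junction
      dir[r - t, c + t] <<- 6  # SW toward the junction
    }
    place(r - L, c - L, d - 1)
    place(r - L, c + L, d - 1)
  }
  root_r <- nr - 1L
  root_c <- (nc + 1L) %/% 2L
  place(root_r, root_c, depth)
  grid_new(dir, cell_size = 100)
}

# Compact landscape used by repeated property tests (properties under
# test are size-independent).
small_spec <- function(seed, ...) {
  landscape_spec(rows = 90, cols = 90, seed = seed, n_settlements = 12,
                 n_communes = 4, min_separation_cells = 6, ...)
}

random_friction <- function(nr, nc, lo = 0.5, hi = 5) {
  matrix(stats::runif(nr * nc, lo, hi), nr, nc)
}
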