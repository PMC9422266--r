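# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package (winding number instead of ray
# crossing, nested scalar loops instead of vectorised sums, queue-based
# flood fill instead of graph components).

# Winding-number point-in-ring test, scalar, boundary-inclusive.
oracle_point_in_ring <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring)
  # boundary first
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- ring[i, 1]; y1 <- ring[i, 2]; x2 <- ring[j, 1]; y2 <- ring[j, 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    t <- if (len2 > 0) max(0, min(1, ((px - x1) * dx + (py - y1) * dy) / len2)) else 0
    if ((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2 <= eps^2) return(TRUE)
  }
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- atan2(ring[i, 2] - py, ring[i, 1] - px)
    b <- atan2(ring[j, 2] - py, ring[j, 1] - px)
    d <- b - a
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    wn <- wn + d
  }
  abs(wn) > pi  # ~2*pi when inside, ~0 outside
}

# even-odd over all rings of a (multi)polygon via winding parity per ring
oracle_point_in_geometry <- function(px, py, geom) {
  if (is.matrix(geom)) geom <- list(list(geom))
  if (is.matrix(geom[[1]])) geom <- list(geom)
  count <- 0L
  for (poly in geom) {
    for (ring in poly) {
      if (oracle_point_in_ring(px, py, ring)) {
        # boundary counts as membership outright
        n <- nrow(ring)
        for (i in seq_len(n)) {
          j <- if (i == n) 1L else i + 1L
          x1 <- ring[i, 1]; y1 <- ring[i, 2]; x2 <- ring[j, 1]; y2 <- ring[j, 2]
          dx <- x2 - x1; dy <- y2 - y1
          len2 <- dx^2 + dy^2
          t <- if (len2 > 0) max(0, min(1, ((px - x1) * dx + (py - y1) * dy) / len2)) else 0
          if ((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2 <= 1e-18) return(TRUE)
        }
        count <- count + 1L
      }
    }
  }
  count %% 2L == 1L
}

# Brute-force rasterization: every pixel centre against every zone, in
# lexicographic zone order, first hit wins.
oracle_rasterize <- function(zones, grid) {
  out <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  ord <- order(zones$zone_id)
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      ctr <- pixel_centers(grid, r, c)
      for (i in ord) {
        if (oracle_point_in_geometry(ctr[1], ctr[2], zones$geometry[[i]])) {
          out[r, c] <- zones$zone_id[i]
          break
        }
      }
    }
  }
  out
}

# labels of a zone_index_raster as a character matrix for comparison
index_to_ids <- function(zidx) {
  ids <- attr(zidx, "zone_ids")
  m <- matrix(NA_character_, nrow(zidx$values), ncol(zidx$values))
  ok <- !is.na(zidx$values)
  m[ok] <- ids[zidx$values[ok]]
  m
}

# Scalar per-pixel apportionment reference: nested loops, no vectorisation.
oracle_apportion <- function(zones, weights, zidx) {
  ids <- attr(zidx, "zone_ids")
  lab <- zidx$values
  w <- weights$values
  out <- matrix(0, nrow(w), ncol(w))
  for (i in seq_len(nrow(zones))) {
    k <- match(zones$zone_id[i], ids)
    W <- 0; npix <- 0
    for (r in seq_len(nrow(w))) for (c in seq_len(ncol(w))) {
      if (!is.na(lab[r, c]) && lab[r, c] == k) {
        W <- W + w[r, c]; npix <- npix + 1
      }
    }
    P <- zones$population[i]
    if (P == 0 || npix == 0) next
    for (r in seq_len(nrow(w))) for (c in seq_len(ncol(w))) {
      if (!is.na(lab[r, c]) && lab[r, c] == k) {
        out[r, c] <- if (W > 0) P * w[r, c] / W else P / npix
      }
    }
  }
  out
}

# Queue-based flood fill counting connected components of each value.
oracle_component_count <- function(mat, connectivity = 4) {
  nr <- nrow(mat); nc <- ncol(mat)
  seen <- matrix(FALSE, nr, nc)
  nbr <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  count <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0]) next
    count <- count + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        r <- cur[1] + nbr[k, 1]; c <- cur[2] + nbr[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && !seen[r, c] &&
            mat[r, c] == mat[cur[1], cur[2]]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# --- small fixture builders ------------------------------------------------

test_grid <- function(n_rows = 4, n_cols = 4, crs = "EPSG:5070") {
  grid_spec(0, n_rows * 30, n_rows = n_rows, n_cols = n_cols, crs_id = crs)
}

# rectangle ring in pixel units on a test grid (r0:r1 x c0:c1, inclusive)
pix_rect <- function(grid, r0, r1, c0, c1) {
  xmin <- grid$origin_x + (c0 - 1) * grid$pixel_size_x
  xmax <- grid$origin_x + c1 * grid$pixel_size_x
  ymax <- grid$origin_y - (r0 - 1) * grid$pixel_size_y
  ymin <- grid$origin_y - r1 * grid$pixel_size_y
  matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax), ncol = 2, byrow = TRUE)
}

# a zone set of vertical strips covering the grid
strip_zones <- function(grid, n_strips, populations = NULL) {
  stopifnot(grid$n_cols %% n_strips == 0)
  w <- grid$n_cols %/% n_strips
  geoms <- lapply(seq_len(n_strips), function(i) {
    pix_rect(grid, 1, grid$n_rows, (i - 1) * w + 1, i * w)
  })
  if (is.null(populations)) populations <- rep(100, n_strips)
  zone_set(sprintf("00-001-Z%02d", seq_len(n_strips)), populations, geoms,
           crs_id = grid$crs_id)
}

random_impervious <- function(grid, p_zero = 0.3) {
  v <- stats::rbeta(grid$n_rows * grid$n_cols, 1.5, 3)
  v[stats::runif(length(v)) < p_zero] <- 0
  impervious_raster(grid, matrix(v, grid$n_rows, grid$n_cols))
}
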