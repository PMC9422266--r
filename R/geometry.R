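# Planar polygon primitives used by rasterization, clipping, zonal overlay
# and the areal-weighting baseline.
#
# Geometry representation (shared across the package):
#   ring      - numeric n x 2 matrix of vertices, not necessarily closed
#               (a closing duplicate vertex is dropped on normalisation)
#   polygon   - list of rings; ring 1 is the outer shell, later rings holes
#   geometry  - list of polygons (a multipolygon); a single polygon is
#               accepted anywhere a geometry is
#
# Point membership everywhere uses the even-odd rule over all rings, with
# points on a ring edge counted as belonging (closed polygons). This matches
# the pixel-center rule used for rasterization and zonal sums.

.EPS_GEOM <- 1e-9

normalize_ring <- function(ring) {
  ring <- as.matrix(ring)
  storage.mode(ring) <- "double"
  if (ncol(ring) != 2L) stop("a ring needs two coordinate columns", call. = FALSE)
  n <- nrow(ring)
  if (n >= 2L && all(abs(ring[1L, ] - ring[n, ]) <= .EPS_GEOM)) {
    ring <- ring[-n, , drop = FALSE]
  }
  if (nrow(ring) < 3L) stop("a ring needs at least 3 distinct vertices", call. = FALSE)
  ring
}

# A geometry may arrive as a bare ring, a polygon, or a multipolygon; return
# the canonical multipolygon form.
normalize_geometry <- function(geom) {
  if (is.matrix(geom)) return(list(list(normalize_ring(geom))))
  if (!is.list(geom) || length(geom) == 0L) {
    stop("invalid geometry", call. = FALSE)
  }
  if (is.matrix(geom[[1L]])) {              # polygon: list of rings
    return(list(lapply(geom, normalize_ring)))
  }
  lapply(geom, function(p) lapply(p, normalize_ring))
}

geometry_rings <- function(geom) {
  unlist(normalize_geometry(geom), recursive = FALSE)
}

# Signed shoelace area of one ring (positive = counter-clockwise).
ring_signed_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Area of a polygon geometry
#'
#' Areas of outer shells minus areas of holes, summed over all polygons of a
#' multipolygon. Ring roles are positional (first ring of each polygon is the
#' shell), as in GeoJSON.
#'
#' @param geom A ring matrix, a polygon (list of rings) or a multipolygon
#'   (list of polygons).
#' @return Area in squared map units.
#' @export
geometry_area <- function(geom) {
  polys <- normalize_geometry(geom)
  total <- 0
  for (p in polys) {
    for (k in seq_along(p)) {
      a <- abs(ring_signed_area(p[[k]]))
      total <- total + if (k == 1L) a else -a
    }
  }
  total
}

geometry_bbox <- function(geom) {
  rings <- geometry_rings(geom)
  xs <- unlist(lapply(rings, function(r) r[, 1L]))
  ys <- unlist(lapply(rings, function(r) r[, 2L]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Vectorised even-odd membership test of many points against one geometry.
# Returns a logical vector: TRUE when the point is inside or on an edge.
points_in_geometry <- function(xs, ys, geom, eps = .EPS_GEOM) {
  rings <- geometry_rings(geom)
  n <- length(xs)
  crossings <- integer(n)
  boundary <- logical(n)
  for (ring in rings) {
    rx <- ring[, 1L]; ry <- ring[, 2L]
    m <- length(rx)
    for (i in seq_len(m)) {
      j <- if (i == 1L) m else i - 1L
      x1 <- rx[j]; y1 <- ry[j]; x2 <- rx[i]; y2 <- ry[i]
      # edge crossing of the rightward ray from each point
      straddles <- (y1 > ys) != (y2 > ys)
      if (any(straddles)) {
        xint <- x1 + (ys - y1) * (x2 - x1) / (y2 - y1)
        hit <- straddles & xs < xint
        crossings[hit] <- crossings[hit] + 1L
      }
      # on-segment test (exact within eps)
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      if (len2 > 0) {
        t <- ((xs - x1) * dx + (ys - y1) * dy) / len2
        t <- pmin(1, pmax(0, t))
        px <- x1 + t * dx; py <- y1 + t * dy
        boundary <- boundary | ((xs - px)^2 + (ys - py)^2 <= eps * eps)
      } else {
        boundary <- boundary | ((xs - x1)^2 + (ys - y1)^2 <= eps * eps)
      }
    }
  }
  (crossings %% 2L == 1L) | boundary
}

# Sutherland-Hodgman clip of one ring against an axis-aligned rectangle.
# The clipper is convex so the result is a single (possibly degenerate)
# ring; returns a matrix with 0 rows when the intersection is empty.
clip_ring_rect <- function(ring, xmin, ymin, xmax, ymax) {
  pts <- ring
  for (side in c("l", "r", "b", "t")) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    keep_fun <- switch(side,
      l = function(x, y) x >= xmin,
      r = function(x, y) x <= xmax,
      b = function(x, y) y >= ymin,
      t = function(x, y) y <= ymax)
    cross_fun <- switch(side,
      l = function(x1, y1, x2, y2) c(xmin, y1 + (y2 - y1) * (xmin - x1) / (x2 - x1)),
      r = function(x1, y1, x2, y2) c(xmax, y1 + (y2 - y1) * (xmax - x1) / (x2 - x1)),
      b = function(x1, y1, x2, y2) c(x1 + (x2 - x1) * (ymin - y1) / (y2 - y1), ymin),
      t = function(x1, y1, x2, y2) c(x1 + (x2 - x1) * (ymax - y1) / (y2 - y1), ymax))
    out <- matrix(numeric(0), 0L, 2L)
    prev <- pts[n, ]
    prev_in <- keep_fun(prev[1L], prev[2L])
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- keep_fun(cur[1L], cur[2L])
      if (cur_in) {
        if (!prev_in) {
          out <- rbind(out, cross_fun(prev[1L], prev[2L], cur[1L], cur[2L]))
        }
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, cross_fun(prev[1L], prev[2L], cur[1L], cur[2L]))
      }
      prev <- cur; prev_in <- cur_in
    }
    pts <- out
  }
  pts
}

# Exact area of geometry intersected with an axis-aligned rectangle.
# Signed per ring: shells add, holes subtract.
geometry_rect_overlap_area <- function(geom, xmin, ymin, xmax, ymax) {
  polys <- normalize_geometry(geom)
  total <- 0
  for (p in polys) {
    for (k in seq_along(p)) {
      clipped <- clip_ring_rect(p[[k]], xmin, ymin, xmax, ymax)
      if (nrow(clipped) >= 3L) {
        a <- abs(ring_signed_area(clipped))
        total <- total + if (k == 1L) a else -a
      }
    }
  }
  total
}

# Convenience: axis-aligned rectangle ring (counter-clockwise).
rect_ring <- function(xmin, ymin, xmax, ymax) {
  matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax),
         ncol = 2L, byrow = TRUE)
}
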