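# Hazard-exposure validation: binarize hazard rasters into at-risk / not-
# at-risk, polygonize connected components, sum population inside risk
# polygons for each candidate population raster, and compare against the
# naive areal-weighting baseline.

#' Binarize a wildfire-hazard raster
#'
#' A categorical wildfire hazard potential raster (five burnable-land
#' classes by default) becomes a boolean at-risk layer: a pixel is at risk
#' iff its class is in `at_risk_classes`. By default classes 3-5 (medium,
#' high, very high) are at risk and the remainder (low, very low) are not.
#' Nodata pixels are not at risk: absence of hazard evidence never creates
#' exposure. Non-burnable legend extensions (water, barren, ...) can be
#' admitted through `legend` and left out of `at_risk_classes`.
#'
#' @param whp Categorical [ugli_raster()] of hazard classes.
#' @param at_risk_classes Codes counted as at risk (default `c(3, 4, 5)`).
#' @param legend All admissible codes (default `1:5`); a valid pixel
#'   outside the legend is an error naming the stray code.
#' @return A boolean raster (values 0/1) of class `binary_raster`.
#' @export
binarize_wildfire <- function(whp, at_risk_classes = c(3, 4, 5), legend = 1:5) {
  stopifnot(inherits(whp, "ugli_raster"))
  v <- valid_values(whp)
  stray <- setdiff(unique(v), legend)
  if (length(stray)) {
    stop("hazard class(es) outside the declared legend: ",
         paste(sort(stray), collapse = ", "), call. = FALSE)
  }
  at_risk <- valid_mask(whp) & whp$values %in% at_risk_classes
  out <- ugli_raster(whp$grid, at_risk * 1, nodata = -9999)
  class(out) <- c("binary_raster", class(out))
  out
}

#' Binarize a flood water-surface-elevation raster
#'
#' A pixel is at risk iff its water surface elevation is strictly positive;
#' zero, negative and nodata pixels are not at risk.
#'
#' @param wse Continuous [ugli_raster()] of water surface elevation.
#' @return A boolean raster (values 0/1) of class `binary_raster`.
#' @export
binarize_flood <- function(wse) {
  stopifnot(inherits(wse, "ugli_raster"))
  at_risk <- valid_mask(wse) & wse$values > 0
  out <- ugli_raster(wse$grid, at_risk * 1, nodata = -9999)
  class(out) <- c("binary_raster", class(out))
  out
}

# Connected-component labels of a logical matrix (TRUE and FALSE pixels
# each grouped among themselves) via the adjacency graph.
label_components <- function(mat, connectivity = 4) {
  nr <- nrow(mat); nc <- ncol(mat)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  edges <- NULL
  add_edges <- function(a, b) {
    a <- as.vector(a); b <- as.vector(b)   # linear indices, not (row,col) pairs
    same <- mat[a] == mat[b]
    rbind(edges, cbind(a[same], b[same]))
  }
  if (nc > 1L) edges <- add_edges(idx[, -nc], idx[, -1L])           # right
  if (nr > 1L) edges <- add_edges(idx[-nr, ], idx[-1L, ])           # down
  if (connectivity == 8 && nr > 1L && nc > 1L) {
    edges <- add_edges(idx[-nr, -nc], idx[-1L, -1L])                # down-right
    edges <- add_edges(idx[-1L, -nc], idx[-nr, -1L])                # up-right
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  igraph::components(g)$membership
}

# Trace the boundary rings of one component (set of pixel indices) on a
# grid. Directed pixel-square edges with the component interior on the
# left; shared interior edges cancel; remaining edges stitch into rings.
# Outer rings come out counter-clockwise (positive area), holes clockwise.
trace_component_rings <- function(pixidx, grid) {
  nr <- grid$n_rows
  rows <- ((pixidx - 1L) %% nr) + 1L
  cols <- ((pixidx - 1L) %/% nr) + 1L
  # lattice vertex key for corner (vx, vy), vx in 0..n_cols, vy in 0..n_rows
  vk <- function(vx, vy) vx * (nr + 1L) + vy
  # per pixel, 4 CCW directed edges (in map coords): BL->BR->TR->TL->BL
  from <- c(vk(cols - 1L, rows), vk(cols, rows),
            vk(cols, rows - 1L), vk(cols - 1L, rows - 1L))
  to <- c(vk(cols, rows), vk(cols, rows - 1L),
          vk(cols - 1L, rows - 1L), vk(cols - 1L, rows))
  keys <- paste(from, to)
  rev_keys <- paste(to, from)
  keep <- !(rev_keys %in% keys)   # interior edges appear in both directions
  from <- from[keep]; to <- to[keep]
  # stitch: map from-vertex -> outgoing edge indices
  out_edges <- split(seq_along(from), from)
  used <- logical(length(from))
  vxy <- function(key) c(key %/% (nr + 1L), key %% (nr + 1L))
  coord <- function(key) {
    v <- vxy(key)
    c(grid$origin_x + v[1L] * grid$pixel_size_x,
      grid$origin_y - v[2L] * grid$pixel_size_y)
  }
  rings <- list()
  for (start in seq_along(from)) {
    if (used[start]) next
    path_keys <- from[start]
    e <- start
    repeat {
      used[e] <- TRUE
      nxt_v <- to[e]
      if (nxt_v == path_keys[1L] && length(path_keys) >= 3L) break
      cand <- out_edges[[as.character(nxt_v)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      if (length(cand) > 1L) {
        # pinch vertex: prefer the sharpest left turn to keep rings simple
        din <- vxy(to[e]) - vxy(from[e])
        turn <- vapply(cand, function(ce) {
          dout <- vxy(to[ce]) - vxy(from[ce])
          din[1L] * dout[2L] - din[2L] * dout[1L]  # lattice cross product
        }, numeric(1))
        # lattice y grows southwards, so a left turn in map coords has
        # negative lattice cross product
        cand <- cand[order(turn)]
      }
      e <- cand[1L]
      path_keys <- c(path_keys, from[e])
    }
    ring <- t(vapply(path_keys, coord, numeric(2)))
    if (nrow(ring) >= 3L) rings[[length(rings) + 1L]] <- ring
  }
  rings
}

# Group traced rings into polygons: each CCW ring is a shell; each CW ring
# is a hole attached to the smallest shell containing a point just inside
# the hole void.
rings_to_polygons <- function(rings, grid) {
  areas <- vapply(rings, ring_signed_area, numeric(1))
  shells <- which(areas > 0)
  holes <- which(areas < 0)
  polys <- lapply(shells, function(s) list(rings[[s]]))
  if (length(holes)) {
    off <- min(grid$pixel_size_x, grid$pixel_size_y) / 4
    shell_area <- abs(areas[shells])
    for (h in holes) {
      ring <- rings[[h]]
      p1 <- ring[1L, ]; p2 <- ring[2L, ]
      d <- p2 - p1; d <- d / sqrt(sum(d^2))
      probe <- (p1 + p2) / 2 + c(d[2L], -d[1L]) * off  # right of edge = void
      containing <- which(vapply(seq_along(shells), function(si) {
        points_in_geometry(probe[1L], probe[2L], rings[[shells[si]]])
      }, logical(1)))
      if (length(containing)) {
        si <- containing[which.min(shell_area[containing])]
        polys[[si]] <- c(polys[[si]], list(rings[[h]]))
      }
    }
  }
  polys
}

#' Polygonize a binary hazard raster
#'
#' Merges adjacent equal-valued pixels into polygons: one polygon per
#' connected component, for both the at-risk and the not-at-risk value.
#' Polygon area equals component pixel count times pixel area; the union
#' of at-risk polygons is exactly the at-risk pixel region.
#'
#' @param mask A `binary_raster` from [binarize_wildfire()] or
#'   [binarize_flood()].
#' @param connectivity 4 (edge-adjacency, default) or 8 (also corners).
#' @param kind Provenance tag recorded on the result (`"wildfire"`,
#'   `"flood"` or any label).
#' @return A data frame of class `hazard_polygons` with columns `poly_id`,
#'   `at_risk`, `n_pixels`, `area`, and attributes `grid`, `pixels` (list
#'   of pixel index vectors), `geometry` (list of multipolygons),
#'   `kind` and `connectivity`.
#' @export
polygonize_binary <- function(mask, connectivity = 4, kind = "hazard") {
  stopifnot(inherits(mask, "binary_raster"))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  vals <- mask$values > 0
  memb <- label_components(vals, connectivity)
  comp_ids <- sort(unique(memb))
  grid <- mask$grid
  pixels <- split(seq_along(memb), memb)
  at_risk <- vapply(pixels, function(p) vals[p[1L]], logical(1))
  geometry <- lapply(pixels, function(p) {
    rings_to_polygons(trace_component_rings(p, grid), grid)
  })
  out <- data.frame(poly_id = sprintf("%s_%04d", kind, seq_along(pixels)),
                    at_risk = unname(at_risk),
                    n_pixels = unname(vapply(pixels, length, integer(1))),
                    stringsAsFactors = FALSE)
  out$area <- out$n_pixels * pixel_area(grid)
  attr(out, "grid") <- grid
  attr(out, "pixels") <- unname(pixels)
  attr(out, "geometry") <- unname(geometry)
  attr(out, "kind") <- kind
  attr(out, "connectivity") <- connectivity
  class(out) <- c("hazard_polygons", "data.frame")
  out
}

#' Sum population inside hazard polygons
#'
#' For each polygon, sums the population of the pixels it contains (pixel
#' centre rule), then forms at-risk and not-at-risk grand totals. When the
#' population raster lives on the polygons' own grid the sums use the exact
#' pixel memberships, so at-risk + not-at-risk totals partition the raster
#' total; a population raster on any other grid (e.g. a third-party gridded
#' product at its native resolution) is overlaid by the centre rule against
#' the polygon geometry.
#'
#' @param pop A [population_raster()] (any grid, same CRS).
#' @param polys A `hazard_polygons` object from [polygonize_binary()].
#' @return List with `per_polygon` (data frame `poly_id`, `at_risk`,
#'   `population`), `at_risk_total`, `not_at_risk_total`, `grand_total`.
#' @export
zonal_population_sum <- function(pop, polys) {
  stopifnot(inherits(pop, "ugli_raster"), inherits(polys, "hazard_polygons"))
  pg <- attr(polys, "grid")
  if (!identical(pop$grid$crs_id, pg$crs_id)) {
    stop(sprintf("population CRS '%s' does not match hazard CRS '%s'",
                 pop$grid$crs_id, pg$crs_id), call. = FALSE)
  }
  v <- pop$values
  v[is.na(v) | v == pop$nodata] <- 0
  if (grids_identical(pop$grid, pg)) {
    sums <- vapply(attr(polys, "pixels"), function(p) sum(v[p]), numeric(1))
  } else {
    ctr <- all_pixel_centers(pop$grid)
    vv <- v[cbind(ctr$row, ctr$col)]
    sums <- vapply(attr(polys, "geometry"), function(geom) {
      bb <- geometry_bbox(geom)
      cand <- ctr$x >= bb["xmin"] & ctr$x <= bb["xmax"] &
              ctr$y >= bb["ymin"] & ctr$y <= bb["ymax"]
      if (!any(cand)) return(0)
      hit <- points_in_geometry(ctr$x[cand], ctr$y[cand], geom)
      sum(vv[cand][hit])
    }, numeric(1))
  }
  per <- data.frame(poly_id = polys$poly_id, at_risk = polys$at_risk,
                    population = sums, stringsAsFactors = FALSE)
  list(per_polygon = per,
       at_risk_total = sum(sums[polys$at_risk]),
       not_at_risk_total = sum(sums[!polys$at_risk]),
       grand_total = sum(sums))
}

#' Areal-weighting population at risk (naive baseline)
#'
#' The baseline assumes people are spread evenly across each zone's area:
#' the population at risk is the sum over zones of P_g times the fraction
#' of the zone's area overlapped by the at-risk region. The overlap is
#' computed exactly by clipping the zone geometry against every at-risk
#' pixel rectangle.
#'
#' @param zones A [zone_set()] (block groups with populations).
#' @param polys A `hazard_polygons` object.
#' @return Population at risk under even-distribution, a single number.
#' @export
areal_weighting_exposure <- function(zones, polys) {
  stopifnot(inherits(zones, "zone_set"), inherits(polys, "hazard_polygons"))
  grid <- attr(polys, "grid")
  if (!identical(zone_crs(zones), grid$crs_id)) {
    stop(sprintf("zone CRS '%s' does not match hazard CRS '%s'",
                 zone_crs(zones), grid$crs_id), call. = FALSE)
  }
  risk_pix <- unlist(attr(polys, "pixels")[polys$at_risk])
  if (length(risk_pix) == 0L) return(0)
  nr <- grid$n_rows
  rows <- ((risk_pix - 1L) %% nr) + 1L
  cols <- ((risk_pix - 1L) %/% nr) + 1L
  px_xmin <- grid$origin_x + (cols - 1L) * grid$pixel_size_x
  px_ymax <- grid$origin_y - (rows - 1L) * grid$pixel_size_y
  total <- 0
  for (i in seq_len(nrow(zones))) {
    P <- zones$population[i]
    geom <- zones$geometry[[i]]
    a_zone <- geometry_area(geom)
    if (a_zone <= 0) {
      if (P > 0) stop("zone ", zones$zone_id[i],
                      " has zero area but positive population", call. = FALSE)
      next
    }
    if (P == 0) next
    bb <- geometry_bbox(geom)
    cand <- which(px_xmin < bb["xmax"] &
                  px_xmin + grid$pixel_size_x > bb["xmin"] &
                  px_ymax > bb["ymin"] &
                  px_ymax - grid$pixel_size_y < bb["ymax"])
    if (!length(cand)) next
    overlap <- sum(vapply(cand, function(k) {
      geometry_rect_overlap_area(geom,
                                 px_xmin[k], px_ymax[k] - grid$pixel_size_y,
                                 px_xmin[k] + grid$pixel_size_x, px_ymax[k])
    }, numeric(1)))
    total <- total + P * overlap / a_zone
  }
  total
}

#' Percent difference against the naive baseline
#'
#' @param method_total Population at risk under the method being compared.
#' @param naive_total Population at risk under areal weighting; must be
#'   positive, otherwise the percent difference is undefined.
#' @return `100 * (method_total - naive_total) / naive_total`.
#' @export
percent_difference <- function(method_total, naive_total) {
  if (!is.numeric(naive_total) || length(naive_total) != 1L ||
      is.na(naive_total) || naive_total <= 0) {
    stop("percent difference undefined: naive total must be > 0", call. = FALSE)
  }
  100 * (method_total - naive_total) / naive_total
}
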