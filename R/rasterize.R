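#' Rasterize zone polygons onto a grid
#'
#' Labels every pixel with the zone whose polygon contains the pixel centre
#' (half-open pixel model, origin at the upper-left). Pixel centres lying in
#' no zone get the `NA` sentinel. A centre lying exactly on a shared zone
#' boundary is assigned deterministically to the lexicographically smallest
#' `zone_id` among the zones whose closed boundary contains it.
#'
#' @param zones A [zone_set()] in the grid's CRS.
#' @param grid A [grid_spec()].
#' @return A zone-index raster: an [ugli_raster()] of class
#'   `zone_index_raster` whose values are integer labels (NA outside all
#'   zones) with a `zone_ids` attribute mapping label `k` to
#'   `zone_ids[k]`.
#' @export
rasterize_zones <- function(zones, grid) {
  stopifnot(inherits(zones, "zone_set"), inherits(grid, "grid_spec"))
  if (nrow(zones) == 0L) stop("empty zone set", call. = FALSE)
  if (!identical(zone_crs(zones), grid$crs_id)) {
    stop(sprintf("zone CRS '%s' does not match grid CRS '%s'",
                 zone_crs(zones), grid$crs_id), call. = FALSE)
  }
  ord <- order(zones$zone_id)  # lexicographic: first match wins ties
  labels <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  for (i in ord) {
    geom <- zones$geometry[[i]]
    bb <- geometry_bbox(geom)
    # candidate pixel window from the zone bbox, padded one pixel
    c0 <- max(1L, floor((bb["xmin"] - grid$origin_x) / grid$pixel_size_x))
    c1 <- min(grid$n_cols, ceiling((bb["xmax"] - grid$origin_x) / grid$pixel_size_x) + 1L)
    r0 <- max(1L, floor((grid$origin_y - bb["ymax"]) / grid$pixel_size_y))
    r1 <- min(grid$n_rows, ceiling((grid$origin_y - bb["ymin"]) / grid$pixel_size_y) + 1L)
    if (c0 > c1 || r0 > r1) next
    rows <- rep(r0:r1, times = c1 - c0 + 1L)
    cols <- rep(c0:c1, each = r1 - r0 + 1L)
    open <- is.na(labels[cbind(rows, cols)])
    if (!any(open)) next
    rows <- rows[open]; cols <- cols[open]
    ctr <- pixel_centers(grid, rows, cols)
    hit <- points_in_geometry(ctr[, 1L], ctr[, 2L], geom)
    if (any(hit)) labels[cbind(rows[hit], cols[hit])] <- i
  }
  # relabel into the zone row order so label k <-> zones$zone_id[k]
  out <- ugli_raster(grid, labels, nodata = -1)
  out$values <- labels  # keep integer semantics; NA is the NONE sentinel
  attr(out, "zone_ids") <- zones$zone_id
  class(out) <- c("zone_index_raster", class(out))
  out
}

zone_index_labels <- function(zidx) attr(zidx, "zone_ids")

#' Clip a raster to a county
#'
#' Crops the grid to the bounding box of the union of the zone geometries,
#' snapped outward to the input grid, and sets pixels whose centres fall
#' outside every zone to nodata. Retained pixel values are never altered.
#'
#' @param r An [ugli_raster()].
#' @param zones A [zone_set()] in the raster's CRS (typically all block
#'   groups of one county; the clip region is their spatial union).
#' @return A raster of the same class with a cropped grid.
#' @export
clip_to_county <- function(r, zones) {
  stopifnot(inherits(r, "ugli_raster"), inherits(zones, "zone_set"))
  g <- r$grid
  if (!identical(zone_crs(zones), g$crs_id)) {
    stop(sprintf("zone CRS '%s' does not match raster CRS '%s'",
                 zone_crs(zones), g$crs_id), call. = FALSE)
  }
  bbs <- lapply(zones$geometry, geometry_bbox)
  bb <- c(xmin = min(vapply(bbs, `[[`, 0, "xmin")),
          ymin = min(vapply(bbs, `[[`, 0, "ymin")),
          xmax = max(vapply(bbs, `[[`, 0, "xmax")),
          ymax = max(vapply(bbs, `[[`, 0, "ymax")))
  # snap bbox outward to pixel edges of the input grid
  c0 <- floor((bb["xmin"] - g$origin_x) / g$pixel_size_x) + 1L
  c1 <- ceiling((bb["xmax"] - g$origin_x) / g$pixel_size_x)
  r0 <- floor((g$origin_y - bb["ymax"]) / g$pixel_size_y) + 1L
  r1 <- ceiling((g$origin_y - bb["ymin"]) / g$pixel_size_y)
  c0 <- max(1L, as.integer(c0)); c1 <- min(g$n_cols, as.integer(c1))
  r0 <- max(1L, as.integer(r0)); r1 <- min(g$n_rows, as.integer(r1))
  if (c0 > c1 || r0 > r1) {
    stop("raster extent does not overlap the zone union", call. = FALSE)
  }
  sub <- r$values[r0:r1, c0:c1, drop = FALSE]
  grid <- grid_spec(origin_x = g$origin_x + (c0 - 1L) * g$pixel_size_x,
                    origin_y = g$origin_y - (r0 - 1L) * g$pixel_size_y,
                    n_rows = r1 - r0 + 1L, n_cols = c1 - c0 + 1L,
                    pixel_size_x = g$pixel_size_x, pixel_size_y = g$pixel_size_y,
                    crs_id = g$crs_id)
  ctr <- all_pixel_centers(grid)
  inside <- logical(length(ctr$x))
  for (geom in zones$geometry) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- points_in_geometry(ctr$x[todo], ctr$y[todo], geom)
  }
  if (!any(inside)) {
    stop("raster extent does not overlap the zone union", call. = FALSE)
  }
  sub[cbind(ctr$row[!inside], ctr$col[!inside])] <- r$nodata
  out <- r
  out$grid <- grid
  out$values <- sub
  out
}
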