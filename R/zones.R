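#' Build a zone set
#'
#' A zone set is the package's vector container: polygons with unique string
#' ids and non-negative populations, all in one projected CRS. Census block
#' groups (apportionment zones) and census blocks (zero-population masking)
#' are both zone sets.
#'
#' @param zone_id Character vector of unique zone identifiers.
#' @param population Non-negative numeric vector, one entry per zone.
#' @param geometry List of geometries, one per zone. Each geometry is a ring
#'   matrix, a polygon (list of rings, first ring the shell) or a
#'   multipolygon (list of polygons); see [geometry_area()].
#' @param crs_id CRS identifier the coordinates live in.
#' @return A data frame of class `zone_set` with columns `zone_id`,
#'   `population` and a `geometry` list-column, carrying a `crs_id`
#'   attribute.
#' @export
zone_set <- function(zone_id, population, geometry, crs_id = "EPSG:5070") {
  zone_id <- as.character(zone_id)
  population <- as.numeric(population)
  if (length(zone_id) == 0L) stop("a zone set needs at least one zone", call. = FALSE)
  if (anyDuplicated(zone_id)) {
    stop("zone ids must be unique; duplicated: ",
         paste(unique(zone_id[duplicated(zone_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(population) != length(zone_id) || length(geometry) != length(zone_id)) {
    stop("zone_id, population and geometry must have equal length", call. = FALSE)
  }
  if (anyNA(population) || any(population < 0)) {
    stop("populations must be non-negative", call. = FALSE)
  }
  geometry <- lapply(geometry, normalize_geometry)
  out <- data.frame(zone_id = zone_id, population = population,
                    stringsAsFactors = FALSE)
  out$geometry <- geometry
  attr(out, "crs_id") <- crs_id
  class(out) <- c("zone_set", "data.frame")
  out
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zones, total population %g, %s\n",
              nrow(x), sum(x$population), attr(x, "crs_id")))
  invisible(x)
}

zone_crs <- function(zones) attr(zones, "crs_id")

#' Read zones from a GeoJSON file
#'
#' Reads Polygon and MultiPolygon features with a text id attribute and a
#' numeric population attribute. The coordinates are taken verbatim: the
#' file must already be in the projected CRS the rest of the inputs use
#' (this package never reprojects).
#'
#' @param path GeoJSON FeatureCollection file.
#' @param zone_id_field,population_field Attribute names (defaults
#'   `"zone_id"`, `"population"`).
#' @param crs_id CRS identifier to record on the result.
#' @return A [zone_set()].
#' @export
read_zones_geojson <- function(path, zone_id_field = "zone_id",
                               population_field = "population",
                               crs_id = "EPSG:5070") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  ids <- character(0); pops <- numeric(0); geoms <- list()
  for (f in gj$features) {
    props <- f$properties
    if (is.null(props[[zone_id_field]]) || is.null(props[[population_field]])) {
      stop(sprintf("feature missing '%s' or '%s' attribute",
                   zone_id_field, population_field), call. = FALSE)
    }
    g <- f$geometry
    coords_to_ring <- function(cc) {
      do.call(rbind, lapply(cc, function(pt) c(pt[[1L]], pt[[2L]])))
    }
    geom <- switch(g$type,
      Polygon = list(lapply(g$coordinates, coords_to_ring)),
      MultiPolygon = lapply(g$coordinates, function(p) lapply(p, coords_to_ring)),
      stop("unsupported geometry type: ", g$type, call. = FALSE))
    ids <- c(ids, as.character(props[[zone_id_field]]))
    pops <- c(pops, as.numeric(props[[population_field]]))
    geoms <- c(geoms, list(geom))
  }
  zone_set(ids, pops, geoms, crs_id = crs_id)
}

#' Write zones to a GeoJSON file
#'
#' @param zones A [zone_set()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  ring_to_coords <- function(ring) {
    closed <- rbind(ring, ring[1L, ])
    lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1L], closed[i, 2L]))
  }
  features <- lapply(seq_len(nrow(zones)), function(i) {
    geom <- zones$geometry[[i]]
    coords <- lapply(geom, function(p) lapply(p, ring_to_coords))
    g <- if (length(coords) == 1L) {
      list(type = "Polygon", coordinates = coords[[1L]])
    } else {
      list(type = "MultiPolygon", coordinates = coords)
    }
    list(type = "Feature",
         properties = list(zone_id = zones$zone_id[i],
                           population = zones$population[i]),
         geometry = g)
  })
  gj <- list(type = "FeatureCollection",
             crs_id = attr(zones, "crs_id"),
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
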