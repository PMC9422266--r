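# Proportional apportionment of zone populations over the residential
# weight surface. The contract is exact conservation: the pixels of a zone
# re-aggregate to the zone's census population.

#' Per-zone weight sums
#'
#' Sums the residential weight surface within each labelled zone. The
#' returned table holds the denominator of the apportionment
#' p_i = P_g * w_i / W_g.
#'
#' @param weights An [impervious_raster()] (the residential weight layer).
#' @param zidx A zone-index raster from [rasterize_zones()] on the same
#'   grid.
#' @param zones Optional [zone_set()] supplying populations, used to set
#'   the fallback flag (a populated zone whose weight sum is zero).
#' @return Data frame with columns `zone_id`, `weight_sum`, `pixel_count`
#'   and (when `zones` is given) `population` and `fallback`.
#' @export
zone_weight_sums <- function(weights, zidx, zones = NULL) {
  stopifnot(inherits(weights, "ugli_raster"),
            inherits(zidx, "zone_index_raster"))
  stop_if_grid_mismatch(weights$grid, zidx$grid,
                        "weight and zone-index rasters")
  ids <- zone_index_labels(zidx)
  lab <- as.vector(zidx$values)
  w <- as.vector(weights$values)
  w[is.na(w) | w == weights$nodata] <- 0
  keep <- !is.na(lab)
  wsum <- rep(0, length(ids))
  count <- rep(0L, length(ids))
  if (any(keep)) {
    t_w <- rowsum(w[keep], lab[keep])
    t_n <- rowsum(rep(1L, sum(keep)), lab[keep])
    at <- as.integer(rownames(t_w))
    wsum[at] <- t_w[, 1L]
    count[at] <- t_n[, 1L]
  }
  out <- data.frame(zone_id = ids, weight_sum = wsum, pixel_count = count,
                    stringsAsFactors = FALSE)
  if (!is.null(zones)) {
    m <- match(out$zone_id, zones$zone_id)
    out$population <- zones$population[m]
    out$fallback <- !is.na(out$population) & out$population > 0 &
      out$weight_sum == 0
  }
  out
}

#' Apportion zone populations across pixels
#'
#' Distributes each zone's population over its pixels in proportion to the
#' residential weight: a pixel with weight w_i in zone g receives
#' P_g * w_i / W_g, where W_g is the zone's weight sum. Per-zone pixel sums
#' reproduce P_g exactly (up to floating-point accumulation), preserving
#' the pycnophylactic property of the source data.
#'
#' Populated zones whose weight sum is zero have no valid pixels to carry
#' people; conservation must still hold, so a fallback applies:
#' \describe{
#'   \item{`uniform_populated_blocks`}{(default) distribute uniformly over
#'     the zone's pixels lying in census blocks with nonzero population
#'     (requires `blocks`); when no such pixel exists, or `blocks` is NULL,
#'     uniformly over all the zone's pixels.}
#'   \item{`uniform`}{distribute uniformly over all the zone's pixels.}
#'   \item{`error`}{stop, naming the zone.}
#'   \item{`drop`}{leave the zone at zero and report it loudly (the output
#'     then under-counts; the dropped ids are in the `fallback_zones`
#'     attribute and a warning).}
#' }
#'
#' @param zones A [zone_set()]; every zone with population > 0 must have at
#'   least one pixel in `zidx`.
#' @param weights Residential weight [impervious_raster()].
#' @param zidx Zone-index raster from [rasterize_zones()] over `zones`.
#' @param fallback_mode One of `"uniform_populated_blocks"`, `"uniform"`,
#'   `"error"`, `"drop"`.
#' @param blocks Optional census-block [zone_set()] backing the default
#'   fallback mode.
#' @return A [population_raster()] with attributes `fallback_zones`
#'   (character vector of zones that needed the fallback) and `zone_report`
#'   (the [zone_weight_sums()] table plus conservation residuals).
#' @export
apportion_population <- function(zones, weights, zidx,
                                 fallback_mode = c("uniform_populated_blocks",
                                                   "uniform", "error", "drop"),
                                 blocks = NULL) {
  fallback_mode <- match.arg(fallback_mode)
  stopifnot(inherits(zones, "zone_set"))
  stop_if_grid_mismatch(weights$grid, zidx$grid,
                        "weight and zone-index rasters")
  if (any(zones$population < 0)) stop("negative population", call. = FALSE)
  ids <- zone_index_labels(zidx)
  tab <- zone_weight_sums(weights, zidx, zones)
  m <- match(zones$zone_id, ids)
  pix <- ifelse(is.na(m), 0L, tab$pixel_count[ifelse(is.na(m), 1L, m)])
  missing_zone <- zones$population > 0 & (is.na(m) | pix == 0L)
  if (any(missing_zone)) {
    stop("populated zone(s) absent from the zone index raster: ",
         paste(zones$zone_id[missing_zone], collapse = ", "), call. = FALSE)
  }

  g <- weights$grid
  lab <- zidx$values
  w <- weights$values
  w[is.na(w) | w == weights$nodata] <- 0
  pop <- matrix(0, g$n_rows, g$n_cols)

  block_lab <- NULL
  block_pops <- NULL
  if (fallback_mode == "uniform_populated_blocks" && !is.null(blocks)) {
    bidx <- suppressWarnings(rasterize_zones(blocks, g))
    block_lab <- bidx$values
    block_pops <- blocks$population
  }

  fallback_zones <- character(0)
  for (i in seq_len(nrow(zones))) {
    P <- zones$population[i]
    if (P == 0) next
    k <- m[i]
    sel <- !is.na(lab) & lab == k
    W <- tab$weight_sum[k]
    if (W > 0) {
      pop[sel] <- P * w[sel] / W
    } else {
      fallback_zones <- c(fallback_zones, zones$zone_id[i])
      if (fallback_mode == "error") {
        stop("zone ", zones$zone_id[i],
             " has population but zero residential weight", call. = FALSE)
      }
      if (fallback_mode == "drop") next
      target <- sel
      if (fallback_mode == "uniform_populated_blocks" && !is.null(block_lab)) {
        inhab <- sel & !is.na(block_lab) & block_pops[block_lab] > 0
        if (any(inhab)) target <- inhab
      }
      pop[target] <- P / sum(target)
    }
  }
  if (length(fallback_zones) && fallback_mode == "drop") {
    warning("dropped populated zones with zero residential weight: ",
            paste(fallback_zones, collapse = ", "), call. = FALSE)
  }

  out <- population_raster(g, pop, nodata = -9999)
  agg <- aggregate_to_zones(out, zidx)
  tab$residual <- agg$total[match(tab$zone_id, agg$zone_id)] -
    ifelse(is.na(tab$population), 0, tab$population)
  if (fallback_mode == "drop") {
    tab$residual[tab$zone_id %in% fallback_zones] <-
      -tab$population[tab$zone_id %in% fallback_zones]
  }
  attr(out, "fallback_zones") <- fallback_zones
  attr(out, "zone_report") <- tab
  out
}

#' Re-aggregate a population raster to its zones
#'
#' Sums pixel values within each labelled zone. Applied to the output of
#' [apportion_population()] this reproduces the input zone populations: the
#' gridded product reports the identical population as the census source
#' when aggregated back to the zone level or above.
#'
#' @param pop A [population_raster()].
#' @param zidx Zone-index raster on the same grid.
#' @return Data frame with columns `zone_id`, `total`.
#' @export
aggregate_to_zones <- function(pop, zidx) {
  stopifnot(inherits(pop, "ugli_raster"), inherits(zidx, "zone_index_raster"))
  stop_if_grid_mismatch(pop$grid, zidx$grid, "population and zone-index rasters")
  ids <- zone_index_labels(zidx)
  lab <- as.vector(zidx$values)
  v <- as.vector(pop$values)
  v[is.na(v) | v == pop$nodata] <- 0
  totals <- rep(0, length(ids))
  keep <- !is.na(lab)
  if (any(keep)) {
    t_v <- rowsum(v[keep], lab[keep])
    totals[as.integer(rownames(t_v))] <- t_v[, 1L]
  }
  data.frame(zone_id = ids, total = totals, stringsAsFactors = FALSE)
}
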