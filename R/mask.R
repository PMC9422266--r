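# Residential masking of the impervious layer.
#
# Three zeroing rules turn raw imperviousness into the "modified impervious
# surface" used as the dasymetric weight: (1) fractions <= a low threshold
# (default 0.01, inclusive) are noise and become 0; (2) road pixels (by
# descriptor class) become 0; (3) pixels in census blocks that had zero
# population become 0 regardless of imperviousness (their impervious cover
# is assumed commercial/industrial). Each rule only writes zeros, so the
# rules are idempotent, value-decreasing and commute.

#' Residential-mask configuration
#'
#' @param low_threshold Impervious fractions less than or equal to this are
#'   zeroed. Default 0.01 (i.e. pixels with at most 1% impervious cover).
#' @param road_classes Descriptor codes zeroed as roads. The default
#'   `c(1, 2, 3)` covers the primary/secondary/tertiary urban-road codes of
#'   the 2016 descriptor legend; non-urban road classes are retained.
#' @param zero_pop_masking Apply the zero-population block rule (default
#'   TRUE).
#' @return An object of class `mask_config`.
#' @export
mask_config <- function(low_threshold = 0.01, road_classes = c(1, 2, 3),
                        zero_pop_masking = TRUE) {
  if (!is.numeric(low_threshold) || length(low_threshold) != 1L ||
      low_threshold < 0 || low_threshold >= 1) {
    stop("low_threshold must lie in [0, 1)", call. = FALSE)
  }
  road_classes <- as.numeric(road_classes)
  structure(list(low_threshold = low_threshold,
                 road_classes = road_classes,
                 zero_pop_masking = isTRUE(zero_pop_masking)),
            class = "mask_config")
}

#' Zero low impervious fractions
#'
#' Sets every pixel with impervious fraction less than or equal to
#' `threshold` to 0 (inclusive comparison); larger values pass unchanged.
#'
#' @param imp An [impervious_raster()].
#' @param threshold Fraction in \[0, 1); default 0.01.
#' @return The filtered [impervious_raster()] with attribute `zeroed_count`.
#' @export
filter_low_impervious <- function(imp, threshold = 0.01) {
  stopifnot(inherits(imp, "impervious_raster"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  out <- imp
  fire <- valid_mask(imp) & imp$values <= threshold & imp$values != 0
  out$values[valid_mask(imp) & imp$values <= threshold] <- 0
  attr(out, "zeroed_count") <- sum(fire)
  out
}

#' Zero road pixels
#'
#' Sets pixels whose descriptor class is in `road_classes` to 0, retaining
#' all non-road impervious surface.
#'
#' @param imp An [impervious_raster()].
#' @param desc A [descriptor_raster()] on the identical grid.
#' @param road_classes Descriptor codes treated as roads.
#' @return The masked [impervious_raster()] with attribute `zeroed_count`.
#' @export
mask_roads <- function(imp, desc, road_classes = c(1, 2, 3)) {
  stopifnot(inherits(imp, "impervious_raster"),
            inherits(desc, "descriptor_raster"))
  stop_if_grid_mismatch(imp$grid, desc$grid, "impervious and descriptor rasters")
  out <- imp
  road <- valid_mask(desc) & desc$values %in% road_classes
  fire <- road & valid_mask(imp) & imp$values != 0
  out$values[road & valid_mask(imp)] <- 0
  attr(out, "zeroed_count") <- sum(fire)
  out
}

#' Zero pixels in zero-population blocks
#'
#' Pixels whose centre falls in a census block with population 0 are set to
#' 0 regardless of their impervious cover. Pixels in populated blocks are
#' untouched. Pixels covered by no block at all are retained unchanged --
#' blocks are expected to tile the county, so a gap is a data problem made
#' visible through a warning and the `uncovered_count` attribute rather
#' than silently deleted population weight.
#'
#' @param imp An [impervious_raster()].
#' @param blocks A [zone_set()] of census blocks (populations from the
#'   finest-grain census) in the grid's CRS.
#' @param grid Grid to evaluate block membership on; defaults to the
#'   raster's own grid and must equal it.
#' @return The masked [impervious_raster()] with attributes `zeroed_count`
#'   and `uncovered_count`.
#' @export
mask_zero_population_blocks <- function(imp, blocks, grid = imp$grid) {
  stopifnot(inherits(imp, "impervious_raster"), inherits(blocks, "zone_set"))
  stop_if_grid_mismatch(imp$grid, grid, "impervious raster and mask grid")
  if (nrow(blocks) == 0L) stop("empty block set", call. = FALSE)
  bidx <- rasterize_zones(blocks, grid)
  lab <- bidx$values
  uncovered <- sum(is.na(lab))
  if (uncovered > 0L) {
    warning(sprintf("%d pixel(s) fall in no census block; retained unchanged",
                    uncovered), call. = FALSE)
  }
  zero_block <- which(blocks$population == 0)
  fire <- !is.na(lab) & lab %in% zero_block
  out <- imp
  hit <- fire & valid_mask(imp)
  attr(out, "zeroed_count") <- sum(hit & imp$values != 0)
  out$values[hit] <- 0
  attr(out, "uncovered_count") <- uncovered
  out
}

#' Build the residential weight surface
#'
#' Composes the three masking rules. The result carries the fraction of
#' impervious surface wherever it is valid to assume population is present,
#' and 0 elsewhere; since every rule only writes zeros the composition is
#' order-independent.
#'
#' @param imp An [impervious_raster()].
#' @param desc A [descriptor_raster()] on the same grid.
#' @param blocks A [zone_set()] of census blocks, or NULL to skip the
#'   zero-population rule.
#' @param cfg A [mask_config()].
#' @return The residential [impervious_raster()] with attribute
#'   `mask_stats`, a list of per-rule zeroed-pixel counts.
#' @export
build_residential_surface <- function(imp, desc, blocks,
                                      cfg = mask_config()) {
  stopifnot(inherits(cfg, "mask_config"))
  out <- filter_low_impervious(imp, cfg$low_threshold)
  stats <- list(low_impervious = attr(out, "zeroed_count"))
  out <- mask_roads(out, desc, cfg$road_classes)
  stats$roads <- attr(out, "zeroed_count")
  stats$zero_population <- 0L
  stats$uncovered <- 0L
  if (cfg$zero_pop_masking && !is.null(blocks)) {
    out <- mask_zero_population_blocks(out, blocks)
    stats$zero_population <- attr(out, "zeroed_count")
    stats$uncovered <- attr(out, "uncovered_count")
  }
  attr(out, "zeroed_count") <- NULL
  attr(out, "uncovered_count") <- NULL
  attr(out, "mask_stats") <- stats
  out
}
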