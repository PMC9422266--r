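# Orchestration of the three workflows (dasymetric mapping, hazard
# validation, fixture simulation) plus YAML run configuration. The
# command-line front-end in inst/cli/ugli.R is a thin wrapper over these
# functions.

#' Build and validate a dasymetric run configuration
#'
#' @param zones Path to block-group GeoJSON (`zone_id` + `population`
#'   attributes).
#' @param blocks Path to block GeoJSON, or NULL to skip zero-population
#'   masking.
#' @param impervious Path to the impervious ASCII grid.
#' @param descriptor Path to the descriptor ASCII grid.
#' @param out_dir Output directory.
#' @param county_code `XX-YYY` code used in the output file name.
#' @param scale_mode Impervious scale dialect (see
#'   [read_impervious_raster()]).
#' @param low_threshold,road_classes,zero_pop_masking See [mask_config()].
#' @param fallback_mode See [apportion_population()].
#' @param crs_id CRS identifier the vector inputs are in.
#' @param out_nodata Nodata value of the written population raster.
#' @return A validated list of class `run_config`.
#' @export
dasymetric_config <- function(zones, blocks, impervious, descriptor,
                              out_dir, county_code = "00-001",
                              scale_mode = "fraction_0_1",
                              low_threshold = 0.01,
                              road_classes = c(1, 2, 3),
                              zero_pop_masking = TRUE,
                              fallback_mode = "uniform_populated_blocks",
                              crs_id = "EPSG:5070",
                              out_nodata = -9999) {
  cfg <- list(workflow = "dasymetric", zones = zones, blocks = blocks,
              impervious = impervious, descriptor = descriptor,
              out_dir = out_dir, county_code = county_code,
              scale_mode = scale_mode, low_threshold = low_threshold,
              road_classes = road_classes,
              zero_pop_masking = zero_pop_masking,
              fallback_mode = fallback_mode, crs_id = crs_id,
              out_nodata = out_nodata)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks referenced input paths exist and options are admissible before
#' any computation starts.
#'
#' @param cfg A `run_config` list.
#' @return `cfg`, invisibly; errors on the first problem found.
#' @export
validate_run_config <- function(cfg) {
  path_fields <- switch(cfg$workflow,
    dasymetric = c("zones", "blocks", "impervious", "descriptor"),
    validate = c("zones", "hazard"),
    character(0))
  for (f in path_fields) {
    p <- cfg[[f]]
    if (is.null(p)) next
    if (!is.character(p) || !file.exists(p)) {
      stop(sprintf("config field '%s': input path does not exist: %s",
                   f, as.character(p)), call. = FALSE)
    }
  }
  if (identical(cfg$workflow, "validate")) {
    for (p in cfg$population_rasters) {
      if (!file.exists(p)) {
        stop("population raster path does not exist: ", p, call. = FALSE)
      }
    }
    if (!cfg$hazard_kind %in% c("wildfire", "flood")) {
      stop("hazard_kind must be 'wildfire' or 'flood'", call. = FALSE)
    }
  }
  if (!is.null(cfg$low_threshold)) mask_config(cfg$low_threshold, cfg$road_classes)
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' Round-tripping a configuration through [write_run_config()] and
#' [read_run_config()] is the identity.
#'
#' @param path YAML file.
#' @param cfg A `run_config`.
#' @return `read_run_config` returns the `run_config`; `write_run_config`
#'   the path, invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$road_classes)) cfg$road_classes <- as.numeric(cfg$road_classes)
  if (!is.null(cfg$population_rasters)) {
    cfg$population_rasters <- unlist(cfg$population_rasters)
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the dasymetric mapping workflow
#'
#' Executes the full per-county pipeline: read inputs, clip the rasters to
#' the county (union of the block groups), apply the three residential
#' masking rules, rasterize the block groups, apportion populations, and
#' write the population grid plus a machine-readable JSON run report. The
#' report carries per-zone population, weight sum, pixel count, fallback
#' flag and conservation residual, the per-rule masked-pixel counts, and
#' the impervious nodata count, so every logged number can be re-derived.
#'
#' @param cfg A `run_config` from [dasymetric_config()] or
#'   [read_run_config()].
#' @param quiet Suppress progress messages (default TRUE).
#' @return Invisibly, a list with `raster_path`, `report_path` and the
#'   `report` itself.
#' @export
run_dasymetric <- function(cfg, quiet = TRUE) {
  validate_run_config(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  zones <- read_zones_geojson(cfg$zones, crs_id = cfg$crs_id)
  blocks <- if (!is.null(cfg$blocks)) {
    read_zones_geojson(cfg$blocks, crs_id = cfg$crs_id)
  }
  imp <- read_impervious_raster(cfg$impervious, cfg$scale_mode)
  nodata_count <- attr(imp, "nodata_count")
  desc <- read_descriptor_raster(cfg$descriptor)
  say("clipping rasters to the county (%d block groups)", nrow(zones))
  imp <- clip_to_county(imp, zones)
  desc <- clip_to_county(desc, zones)
  mcfg <- mask_config(cfg$low_threshold, cfg$road_classes, cfg$zero_pop_masking)
  res <- build_residential_surface(imp, desc, blocks, mcfg)
  stats <- attr(res, "mask_stats")
  say("masked pixels: %d low-impervious, %d road, %d zero-population block",
      stats$low_impervious, stats$roads, stats$zero_population)
  zidx <- rasterize_zones(zones, imp$grid)
  pop <- apportion_population(zones, res, zidx,
                              fallback_mode = cfg$fallback_mode,
                              blocks = blocks)
  pop$nodata <- cfg$out_nodata
  raster_path <- write_population_raster(pop, cfg$out_dir, cfg$county_code)
  tab <- attr(pop, "zone_report")
  report <- list(county_code = cfg$county_code,
                 impervious_nodata_count = nodata_count,
                 mask_stats = stats,
                 fallback_zones = attr(pop, "fallback_zones"),
                 max_abs_conservation_residual = max(abs(tab$residual)),
                 zones = tab)
  report_path <- file.path(cfg$out_dir,
                           sprintf("ugli_report_%s.json", cfg$county_code))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  say("wrote %s", raster_path)
  invisible(list(raster_path = raster_path, report_path = report_path,
                 report = report))
}

#' Build a validation run configuration
#'
#' @param hazard Path to the hazard ASCII grid.
#' @param hazard_kind `"wildfire"` or `"flood"`.
#' @param population_rasters Named character vector of method-name = path
#'   pairs; each raster is overlaid on its native grid.
#' @param zones Path to block-group GeoJSON (the areal-weighting baseline).
#' @param out Output CSV path.
#' @param connectivity Polygonization connectivity (4 or 8).
#' @param at_risk_classes Wildfire classes counted as at risk.
#' @param crs_id CRS identifier of the vector input.
#' @return A validated `run_config`.
#' @export
validation_config <- function(hazard, hazard_kind, population_rasters,
                              zones, out, connectivity = 4,
                              at_risk_classes = c(3, 4, 5),
                              crs_id = "EPSG:5070") {
  if (length(population_rasters) == 0L) {
    stop("at least one named population raster is required", call. = FALSE)
  }
  if (is.null(names(population_rasters)) ||
      any(!nzchar(names(population_rasters)))) {
    stop("population rasters must be named (method=path)", call. = FALSE)
  }
  cfg <- list(workflow = "validate", hazard = hazard,
              hazard_kind = hazard_kind,
              population_rasters = population_rasters, zones = zones,
              out = out, connectivity = connectivity,
              at_risk_classes = at_risk_classes, crs_id = crs_id)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Run the hazard-exposure validation workflow
#'
#' Binarizes the hazard raster, polygonizes it, computes the population at
#' risk for every named population raster and for the areal-weighting
#' baseline, and writes an exposure table with percent differences against
#' the baseline. When the hazard contains no at-risk pixel all totals are
#' zero and the percent difference is reported as `NA` with a warning.
#'
#' @param cfg A `run_config` from [validation_config()].
#' @param county_id Label for the county column (default `"county"`).
#' @return The exposure table (also written to `cfg$out` as CSV):
#'   columns `county_id`, `method`, `population_at_risk`,
#'   `pct_diff_vs_naive`.
#' @export
run_validation <- function(cfg, county_id = "county") {
  validate_run_config(cfg)
  hz <- read_ascii_raster(cfg$hazard)
  mask <- if (cfg$hazard_kind == "wildfire") {
    binarize_wildfire(hz, at_risk_classes = cfg$at_risk_classes)
  } else {
    binarize_flood(hz)
  }
  polys <- polygonize_binary(mask, connectivity = cfg$connectivity,
                             kind = cfg$hazard_kind)
  zones <- read_zones_geojson(cfg$zones, crs_id = cfg$crs_id)
  naive <- areal_weighting_exposure(zones, polys)
  methods <- names(cfg$population_rasters)
  totals <- vapply(methods, function(mname) {
    pop <- read_ascii_raster(cfg$population_rasters[[mname]])
    pop <- population_raster(pop$grid, pmax(pop$values, 0), nodata = pop$nodata)
    zonal_population_sum(pop, polys)$at_risk_total
  }, numeric(1))
  if (naive > 0) {
    pct <- vapply(totals, percent_difference, numeric(1), naive_total = naive)
    naive_pct <- 0
  } else {
    warning("no population at risk under the naive baseline; percent differences undefined",
            call. = FALSE)
    pct <- rep(NA_real_, length(totals))
    naive_pct <- NA_real_
  }
  out <- data.frame(county_id = county_id,
                    method = c(methods, "naive"),
                    population_at_risk = c(unname(totals), naive),
                    pct_diff_vs_naive = c(unname(pct), naive_pct),
                    stringsAsFactors = FALSE)
  if (!is.null(cfg$out)) {
    utils::write.csv(out, cfg$out, row.names = FALSE)
  }
  out
}

#' Write a synthetic-county fixture set to disk
#'
#' Materialises a generated county as files in the formats the pipeline
#' reads: block-group and block GeoJSON, impervious / descriptor / truth
#' ASCII grids, and optional hazard grids.
#'
#' @param cfg A [synthetic_county_config()].
#' @param out_dir Output directory (created if needed).
#' @param hazards Character subset of `c("wildfire", "flood")` to also
#'   generate, or NULL.
#' @return Invisibly, a named list of written paths plus the
#'   `synthetic_county` object.
#' @export
simulate_fixtures <- function(cfg, out_dir, hazards = c("wildfire", "flood")) {
  county <- generate_synthetic_county(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    zones = file.path(out_dir, "block_groups.geojson"),
    blocks = file.path(out_dir, "blocks.geojson"),
    impervious = file.path(out_dir, "impervious.asc"),
    descriptor = file.path(out_dir, "descriptor.asc"),
    truth = file.path(out_dir, "truth_population.asc"))
  write_zones_geojson(county$zones, paths$zones)
  write_zones_geojson(county$blocks, paths$blocks)
  write_ascii_raster(county$impervious, paths$impervious)
  write_ascii_raster(county$descriptor, paths$descriptor)
  write_ascii_raster(county$truth, paths$truth)
  for (hk in hazards) {
    p <- file.path(out_dir, sprintf("%s.asc", hk))
    write_ascii_raster(generate_hazard_raster(county$grid, hk,
                                              seed = cfg$seed + 1L), p)
    paths[[hk]] <- p
  }
  invisible(c(paths, list(county = county)))
}
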