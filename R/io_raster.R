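# Raster file I/O.
#
# Rasters travel as Esri ASCII grids (.asc): a plain-text header carrying the
# full geotransform (llcorner + cell size) followed by rows of values, north
# row first. The CRS identifier rides in a .prj sidecar next to the grid, as
# is conventional for this format. Values are written at full double
# precision (%.17g) so write-then-read round-trips are bit-compatible.

prj_path_for <- function(path) sub("\\.[^.]+$", ".prj", path)

#' Write a raster as an Esri ASCII grid
#'
#' Writes `<path>` plus a `.prj` sidecar holding the CRS identifier. Square
#' pixels use the standard `cellsize` header; rectangular pixels use the
#' `dx`/`dy` extension.
#'
#' @param r An [ugli_raster()].
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_raster <- function(r, path) {
  stopifnot(inherits(r, "ugli_raster"))
  g <- r$grid
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(v) sprintf("%.17g", v)
  writeLines(c(sprintf("ncols %d", g$n_cols),
               sprintf("nrows %d", g$n_rows),
               sprintf("xllcorner %s", num(g$origin_x)),
               sprintf("yllcorner %s", num(g$origin_y - g$n_rows * g$pixel_size_y))),
             con)
  if (g$pixel_size_x == g$pixel_size_y) {
    writeLines(sprintf("cellsize %s", num(g$pixel_size_x)), con)
  } else {
    writeLines(c(sprintf("dx %s", num(g$pixel_size_x)),
                 sprintf("dy %s", num(g$pixel_size_y))), con)
  }
  writeLines(sprintf("NODATA_value %s", num(r$nodata)), con)
  vals <- r$values
  vals[is.na(vals)] <- r$nodata
  for (i in seq_len(g$n_rows)) {
    writeLines(paste(num(vals[i, ]), collapse = " "), con)
  }
  writeLines(r$grid$crs_id, prj_path_for(path))
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path `.asc` file; its `.prj` sidecar supplies the CRS identifier.
#' @param crs_id Override for the CRS when no sidecar exists. When neither
#'   is available the raster is refused as unprojected.
#' @return An [ugli_raster()].
#' @export
read_ascii_raster <- function(path, crs_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "dx", "dy", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2L])
      i <- i + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner")) {
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header: missing ", k, call. = FALSE)
  }
  dx <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dx
  dy <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dy
  if (is.null(dx) || is.null(dy)) stop("malformed ASCII grid header: no cell size", call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  if (is.null(crs_id)) {
    prj <- prj_path_for(path)
    if (!file.exists(prj)) {
      stop("unprojected raster: no CRS sidecar for ", path, call. = FALSE)
    }
    crs_id <- trimws(readLines(prj, n = 1L))
  }
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  data_lines <- lines[seq(i, length.out = n_rows)]
  vals <- t(vapply(data_lines, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  }, numeric(n_cols), USE.NAMES = FALSE))
  grid <- grid_spec(origin_x = hdr$xllcorner,
                    origin_y = hdr$yllcorner + n_rows * dy,
                    n_rows = n_rows, n_cols = n_cols,
                    pixel_size_x = dx, pixel_size_y = dy,
                    crs_id = crs_id)
  ugli_raster(grid, vals, nodata = nodata)
}

#' Read an impervious-surface raster
#'
#' Reads a single-band impervious surface grid and rescales it to fraction
#' in \[0, 1\]. The source product's 0-100 integer-percent dialect is handled
#' by `scale_mode = "percent_0_100"`. Nodata pixels are treated as
#' uninhabitable: they become fraction 0, and the count of such pixels is
#' recorded in the `nodata_count` attribute of the result (and surfaced in
#' run reports).
#'
#' @param path Single-band ASCII grid in a projected CRS (a missing CRS
#'   sidecar is an error).
#' @param scale_mode `"percent_0_100"` or `"fraction_0_1"`.
#' @return An [impervious_raster()] with attribute `nodata_count`.
#' @export
read_impervious_raster <- function(path, scale_mode = c("percent_0_100",
                                                        "fraction_0_1")) {
  scale_mode <- match.arg(scale_mode)
  r <- read_ascii_raster(path)
  nd <- !valid_mask(r)
  vals <- r$values
  vals[nd] <- 0
  if (scale_mode == "percent_0_100") vals <- vals / 100
  if (any(vals < 0 | vals > 1)) {
    stop(sprintf("impervious values outside declared scale after rescale: range [%g, %g]",
                 min(vals), max(vals)), call. = FALSE)
  }
  out <- impervious_raster(r$grid, vals, nodata = r$nodata)
  attr(out, "nodata_count") <- sum(nd)
  out
}

#' Read a descriptor raster
#'
#' @param path Single-band ASCII grid of integer class codes.
#' @param code_list Optional admissible code list (see [descriptor_raster()]).
#' @return A [descriptor_raster()].
#' @export
read_descriptor_raster <- function(path, code_list = NULL) {
  r <- read_ascii_raster(path)
  descriptor_raster(r$grid, r$values, nodata = r$nodata, code_list = code_list)
}

#' Write a county population raster
#'
#' Writes the dasymetric output for one county. The file name embeds the
#' county FIPS code in the `XX-YYY` form (two-character state, hyphen,
#' three-character county), following the naming convention of the published
#' county products.
#'
#' @param pop A [population_raster()].
#' @param dir Output directory (created if absent).
#' @param county_code County code matching `XX-YYY`.
#' @param prefix File name prefix; the file written is
#'   `<prefix>_<county_code>.asc`.
#' @return Path of the written grid, invisibly.
#' @export
write_population_raster <- function(pop, dir, county_code, prefix = "ugli_pop") {
  stopifnot(inherits(pop, "population_raster"))
  if (!grepl("^[A-Za-z0-9]{2}-[A-Za-z0-9]{3}$", county_code)) {
    stop("malformed county code (want XX-YYY): ", county_code, call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s.asc", prefix, county_code))
  write_ascii_raster(pop, path)
  invisible(path)
}
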