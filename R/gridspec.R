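#' Define a raster grid
#'
#' A `grid_spec` describes a regular, axis-aligned raster grid in a projected
#' equal-area coordinate reference system. Rows run north to south, columns
#' west to east; the origin is the upper-left corner of the upper-left pixel.
#' At the default 30-m pixel size each pixel covers 900 m2 of ground area.
#'
#' @param origin_x,origin_y Coordinates (map units, metres) of the grid's
#'   upper-left corner.
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param pixel_size_x,pixel_size_y Pixel edge lengths in metres (default 30).
#' @param crs_id Identifier of the projected CRS the coordinates live in
#'   (e.g. `"EPSG:5070"`, the CONUS Albers equal-area code). Purely an
#'   identity tag: the package never reprojects, it only checks that layers
#'   agree.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 300, n_rows = 10, n_cols = 10)
#' pixel_area(g)  # 900
#' @export
grid_spec <- function(origin_x, origin_y, n_rows, n_cols,
                      pixel_size_x = 30, pixel_size_y = 30,
                      crs_id = "EPSG:5070") {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y),
            length(origin_x) == 1L, length(origin_y) == 1L)
  if (!is.numeric(pixel_size_x) || pixel_size_x <= 0 ||
      !is.numeric(pixel_size_y) || pixel_size_y <= 0) {
    stop("pixel sizes must be positive", call. = FALSE)
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("grid dimensions must be positive integers", call. = FALSE)
  }
  if (!is.character(crs_id) || length(crs_id) != 1L || !nzchar(crs_id)) {
    stop("crs_id must be a non-empty string", call. = FALSE)
  }
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 n_rows = n_rows, n_cols = n_cols,
                 pixel_size_x = as.numeric(pixel_size_x),
                 pixel_size_y = as.numeric(pixel_size_y),
                 crs_id = crs_id),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels of %g x %g m, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$pixel_size_x, x$pixel_size_y,
              x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

#' Ground area of one pixel
#'
#' @param grid A [grid_spec()].
#' @return Pixel area in square map units (m2 for metric CRSs).
#' @export
pixel_area <- function(grid) grid$pixel_size_x * grid$pixel_size_y

#' Pixel centre coordinates
#'
#' Closed-form centre of pixel (row, col) under the half-open pixel model:
#' pixel (r, c) spans x in \[origin_x + (c-1) dx, origin_x + c dx) and
#' y in (origin_y - r dy, origin_y - (r-1) dy\].
#'
#' @param grid A [grid_spec()].
#' @param row,col 1-based pixel indices (vectorised).
#' @return A two-column matrix of (x, y) centre coordinates.
#' @export
pixel_centers <- function(grid, row, col) {
  cbind(x = grid$origin_x + (col - 0.5) * grid$pixel_size_x,
        y = grid$origin_y - (row - 0.5) * grid$pixel_size_y)
}

#' Centre coordinates of every pixel in a grid
#'
#' @param grid A [grid_spec()].
#' @return List with vectors `x`, `y`, `row`, `col`, one entry per pixel in
#'   column-major (R matrix) order.
#' @keywords internal
all_pixel_centers <- function(grid) {
  row <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  ctr <- pixel_centers(grid, row, col)
  list(x = ctr[, 1L], y = ctr[, 2L], row = row, col = col)
}

grids_identical <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$pixel_size_x - b$pixel_size_x) <= tol &&
    abs(a$pixel_size_y - b$pixel_size_y) <= tol &&
    identical(a$crs_id, b$crs_id)
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!grids_identical(a, b)) {
    stop(sprintf("%s are not on the same grid", what), call. = FALSE)
  }
  invisible(TRUE)
}
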