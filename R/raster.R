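#' Create an in-memory raster
#'
#' The common carrier for all gridded layers: a numeric matrix of shape
#' (n_rows, n_cols) bound to a [grid_spec()] plus a nodata sentinel. Values
#' equal to the sentinel are invalid; everything else is data.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix with `grid$n_rows` rows and `grid$n_cols`
#'   columns. Row 1 is the northernmost row.
#' @param nodata Sentinel value marking invalid pixels (default -9999). Must
#'   not collide with a valid value.
#' @return An object of class `ugli_raster`.
#' @export
ugli_raster <- function(grid, values, nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(values)) values <- matrix(values, grid$n_rows, grid$n_cols)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("values shape does not match grid dimensions", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, nodata = as.numeric(nodata)),
            class = "ugli_raster")
}

#' @export
print.ugli_raster <- function(x, ...) {
  v <- valid_values(x)
  cat(sprintf("<%s> %d x %d, nodata = %g", class(x)[1L],
              x$grid$n_rows, x$grid$n_cols, x$nodata))
  if (length(v)) cat(sprintf(", value range [%g, %g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Logical mask of valid (non-nodata) pixels
#' @param r An `ugli_raster`.
#' @keywords internal
valid_mask <- function(r) !is.na(r$values) & r$values != r$nodata

valid_values <- function(r) r$values[valid_mask(r)]

#' Impervious-surface-fraction raster
#'
#' An [ugli_raster()] whose valid values are impervious surface fractions in
#' \[0, 1\]. This layer supplies the per-pixel dasymetric weight.
#'
#' @inheritParams ugli_raster
#' @return An object of classes `impervious_raster`, `ugli_raster`.
#' @export
impervious_raster <- function(grid, values, nodata = -9999) {
  r <- ugli_raster(grid, values, nodata)
  v <- valid_values(r)
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop(sprintf("impervious fractions outside [0,1]: range [%g, %g]",
                 min(v), max(v)), call. = FALSE)
  }
  class(r) <- c("impervious_raster", class(r))
  r
}

#' Impervious-surface descriptor raster
#'
#' Categorical companion to the impervious fraction layer: integer class
#' codes describing the source of imperviousness (road classes, non-road
#' urban, energy, etc.).
#'
#' @inheritParams ugli_raster
#' @param code_list Optional integer vector of admissible codes; when given,
#'   any valid pixel outside it is an error.
#' @return An object of classes `descriptor_raster`, `ugli_raster`.
#' @export
descriptor_raster <- function(grid, values, nodata = -9999, code_list = NULL) {
  r <- ugli_raster(grid, values, nodata)
  v <- valid_values(r)
  if (length(v) && any(v != round(v) | v < 0)) {
    stop("descriptor codes must be non-negative integers", call. = FALSE)
  }
  if (!is.null(code_list)) {
    stray <- setdiff(unique(v), code_list)
    if (length(stray)) {
      stop("descriptor codes outside declared code list: ",
           paste(stray, collapse = ", "), call. = FALSE)
    }
  }
  class(r) <- c("descriptor_raster", class(r))
  r
}

#' Per-pixel population raster
#'
#' Estimated persons per pixel (fractional values allowed: at the default
#' 30-m grid each value is the population of a 900 m2 cell). Valid values
#' must be non-negative.
#'
#' @inheritParams ugli_raster
#' @return An object of classes `population_raster`, `ugli_raster`.
#' @export
population_raster <- function(grid, values, nodata = -9999) {
  r <- ugli_raster(grid, values, nodata)
  v <- valid_values(r)
  if (length(v) && min(v) < 0) {
    stop("population values must be non-negative", call. = FALSE)
  }
  class(r) <- c("population_raster", class(r))
  r
}
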