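# Seeded synthetic counties.
#
# The generator emulates the structure of the real inputs at desk scale:
# a rectangular county of 30-m pixels, census blocks tiling the grid,
# block groups as unions of whole blocks, a zero-inflated-Beta impervious
# fraction field, a descriptor layer with painted road corridors, and a
# ground-truth population raster placed proportionally on the residential
# (post-mask) surface so the pipeline's assumptions hold exactly. Fixtures
# are structural stand-ins, not demographic ones.

#' Configuration for a synthetic county
#'
#' @param n_rows,n_cols Grid dimensions in pixels (default 48 x 48,
#'   i.e. ~1.4 x 1.4 km of 30-m pixels).
#' @param block_rows,block_cols Number of block rows/columns; blocks are
#'   rectangles tiling the grid, so `n_rows` (`n_cols`) must be divisible
#'   by `block_rows` (`block_cols`).
#' @param blocks_per_group Whole blocks per block group (consecutive in
#'   row-major block order); must divide the block count.
#' @param zero_pop_fraction Fraction of blocks forced to zero population
#'   (default 0.15, a typical share of uninhabited blocks).
#' @param p_zero Zero-inflation probability of the impervious model: the
#'   chance a pixel has no impervious surface at all (default 0.35).
#' @param beta_shape1,beta_shape2 Beta shape parameters for nonzero
#'   impervious fractions (default 1.2, 3 - right-skewed, mostly low
#'   cover with occasional dense development).
#' @param road_count,road_width Number and pixel width of straight road
#'   corridors painted into the descriptor (default 2 corridors, 1 pixel).
#' @param total_population County population placed on the grid (default
#'   10000).
#' @param misspecified Place a small share of population onto masked
#'   pixels, violating the residential assumption, to exercise error
#'   reporting (default FALSE).
#' @param county_code County FIPS-style code used as id prefix.
#' @param crs_id CRS identifier stamped on all layers.
#' @param seed Integer seed; the whole county is a deterministic function
#'   of the configuration.
#' @return An object of class `synthetic_county_config`.
#' @export
synthetic_county_config <- function(n_rows = 48, n_cols = 48,
                                    block_rows = 8, block_cols = 8,
                                    blocks_per_group = 4,
                                    zero_pop_fraction = 0.15,
                                    p_zero = 0.35,
                                    beta_shape1 = 1.2, beta_shape2 = 3,
                                    road_count = 2, road_width = 1,
                                    total_population = 10000,
                                    misspecified = FALSE,
                                    county_code = "00-001",
                                    crs_id = "EPSG:5070",
                                    seed = 1L) {
  if (n_rows %% block_rows != 0 || n_cols %% block_cols != 0) {
    stop("blocks must tile the grid: block_rows | n_rows and block_cols | n_cols",
         call. = FALSE)
  }
  n_blocks <- block_rows * block_cols
  if (n_blocks %% blocks_per_group != 0) {
    stop("blocks_per_group must divide the block count", call. = FALSE)
  }
  for (p in c(zero_pop_fraction, p_zero)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  if (total_population < 0) stop("total population must be >= 0", call. = FALSE)
  structure(as.list(environment())[c(
    "n_rows", "n_cols", "block_rows", "block_cols", "blocks_per_group",
    "zero_pop_fraction", "p_zero", "beta_shape1", "beta_shape2",
    "road_count", "road_width", "total_population", "misspecified",
    "county_code", "crs_id", "seed")],
    class = "synthetic_county_config")
}

# rectangle geometry for a block spanning pixel rows r0:r1, cols c0:c1
block_rect <- function(grid, r0, r1, c0, c1) {
  rect_ring(grid$origin_x + (c0 - 1L) * grid$pixel_size_x,
            grid$origin_y - r1 * grid$pixel_size_y,
            grid$origin_x + c1 * grid$pixel_size_x,
            grid$origin_y - (r0 - 1L) * grid$pixel_size_y)
}

#' Generate a synthetic county
#'
#' Builds all layers of one county fixture. Ground truth is constructed
#' proportional to the post-mask residential surface (after low-fraction
#' filtering at the default 0.01 threshold, road removal, and the chosen
#' zero-population blocks), and block and block-group populations are
#' aggregates of that truth, so applying the masking and apportionment
#' pipeline to the generated inputs recovers the truth raster up to
#' floating-point error. With `misspecified = TRUE` a small share of
#' population is moved onto masked pixels instead, so recovery errors
#' become nonzero and must be surfaced by [recovery_report()].
#'
#' @param cfg A [synthetic_county_config()].
#' @return An object of class `synthetic_county`: a list with `zones`
#'   (block groups), `blocks`, `impervious`, `descriptor`, `truth`
#'   (a [population_raster()]), `grid`, and the `config`.
#' @export
generate_synthetic_county <- function(cfg = synthetic_county_config()) {
  stopifnot(inherits(cfg, "synthetic_county_config"))
  set.seed(cfg$seed)
  grid <- grid_spec(origin_x = 0, origin_y = cfg$n_rows * 30,
                    n_rows = cfg$n_rows, n_cols = cfg$n_cols,
                    crs_id = cfg$crs_id)

  # impervious fractions: zero-inflated Beta
  n_pix <- cfg$n_rows * cfg$n_cols
  frac <- stats::rbeta(n_pix, cfg$beta_shape1, cfg$beta_shape2)
  frac[stats::runif(n_pix) < cfg$p_zero] <- 0
  imp <- impervious_raster(grid, matrix(frac, cfg$n_rows, cfg$n_cols))

  # descriptor: non-road urban code 20 everywhere, road corridors 1/2/3
  desc_vals <- matrix(20, cfg$n_rows, cfg$n_cols)
  road_codes <- c(1, 2, 3)
  if (cfg$road_count > 0) {
    for (k in seq_len(cfg$road_count)) {
      code <- road_codes[(k - 1L) %% 3L + 1L]
      if (k %% 2L == 1L) {                      # horizontal corridor
        r0 <- sample(cfg$n_rows - cfg$road_width + 1L, 1L)
        desc_vals[r0:(r0 + cfg$road_width - 1L), ] <- code
      } else {                                  # vertical corridor
        c0 <- sample(cfg$n_cols - cfg$road_width + 1L, 1L)
        desc_vals[, c0:(c0 + cfg$road_width - 1L)] <- code
      }
    }
  }
  desc <- descriptor_raster(grid, desc_vals)

  # blocks tile the grid; groups are runs of consecutive blocks
  bh <- cfg$n_rows %/% cfg$block_rows   # block height in pixels
  bw <- cfg$n_cols %/% cfg$block_cols
  n_blocks <- cfg$block_rows * cfg$block_cols
  block_geom <- vector("list", n_blocks)
  block_pix <- vector("list", n_blocks)
  pix_idx <- matrix(seq_len(n_pix), cfg$n_rows, cfg$n_cols)
  k <- 0L
  for (br in seq_len(cfg$block_rows)) {
    for (bc in seq_len(cfg$block_cols)) {
      k <- k + 1L
      r0 <- (br - 1L) * bh + 1L; r1 <- br * bh
      c0 <- (bc - 1L) * bw + 1L; c1 <- bc * bw
      block_geom[[k]] <- block_rect(grid, r0, r1, c0, c1)
      block_pix[[k]] <- as.vector(pix_idx[r0:r1, c0:c1])
    }
  }
  n_zero <- round(cfg$zero_pop_fraction * n_blocks)
  zero_blocks <- if (n_zero > 0) sample(n_blocks, n_zero) else integer(0)

  # residential surface under the default mask rules and chosen zero blocks
  w <- imp$values
  w[w <= 0.01] <- 0
  w[desc_vals %in% road_codes] <- 0
  for (b in zero_blocks) w[block_pix[[b]]] <- 0

  if (cfg$total_population > 0 && sum(w) == 0) {
    stop("infeasible config: positive population but no residential pixel left",
         call. = FALSE)
  }
  truth_vals <- matrix(0, cfg$n_rows, cfg$n_cols)
  if (cfg$total_population > 0) {
    truth_vals <- cfg$total_population * w / sum(w)
    if (cfg$misspecified) {
      # move 2% of people onto masked (zero-weight) pixels
      masked <- setdiff(which(w == 0), unlist(block_pix[zero_blocks]))
      if (length(masked)) {
        stray <- sample(masked, min(10L, length(masked)))
        moved <- 0.02 * cfg$total_population
        truth_vals <- truth_vals * (1 - 0.02)
        truth_vals[stray] <- truth_vals[stray] + moved / length(stray)
      }
    }
  }
  truth <- population_raster(grid, truth_vals)

  # block populations aggregate the truth; zero blocks are exactly zero
  block_pop <- vapply(block_pix, function(p) sum(truth_vals[p]), numeric(1))
  block_ids <- sprintf("%s-B%03d", cfg$county_code, seq_len(n_blocks))
  blocks <- zone_set(block_ids, block_pop, block_geom, crs_id = cfg$crs_id)

  # block groups: consecutive blocks in row-major order, as multipolygons
  n_groups <- n_blocks %/% cfg$blocks_per_group
  grp_of_block <- rep(seq_len(n_groups), each = cfg$blocks_per_group)
  group_geom <- lapply(seq_len(n_groups), function(gi) {
    # multipolygon: one single-ring polygon per member block
    lapply(which(grp_of_block == gi), function(b) list(block_geom[[b]]))
  })
  group_pop <- as.vector(rowsum(block_pop, grp_of_block))
  group_ids <- sprintf("%s-G%03d", cfg$county_code, seq_len(n_groups))
  zones <- zone_set(group_ids, group_pop, group_geom, crs_id = cfg$crs_id)

  structure(list(zones = zones, blocks = blocks, impervious = imp,
                 descriptor = desc, truth = truth, grid = grid,
                 zero_pop_blocks = block_ids[zero_blocks], config = cfg),
            class = "synthetic_county")
}

#' Generate a synthetic hazard raster
#'
#' Stands in for the real hazard products: `"wildfire"` yields a
#' categorical raster with classes 1-5 obtained by quantile-slicing a
#' smooth random field (sum of Gaussian bumps); `"flood"` yields a
#' continuous water-surface-elevation raster, positive on a contiguous
#' low-elevation region covering roughly `params$inundated_fraction` of
#' the grid and non-positive elsewhere.
#'
#' @param grid A [grid_spec()].
#' @param kind `"wildfire"` or `"flood"`.
#' @param params For flood, `list(inundated_fraction = ...)` (default 0.3);
#'   for wildfire, `list(n_bumps = ...)` (default 5).
#' @param seed Integer seed.
#' @return An [ugli_raster()].
#' @export
generate_hazard_raster <- function(grid, kind = c("wildfire", "flood"),
                                   params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  ctr <- all_pixel_centers(grid)
  if (kind == "wildfire") {
    n_bumps <- if (is.null(params$n_bumps)) 5L else params$n_bumps
    ext_x <- grid$n_cols * grid$pixel_size_x
    ext_y <- grid$n_rows * grid$pixel_size_y
    field <- numeric(length(ctr$x))
    for (b in seq_len(n_bumps)) {
      cx <- grid$origin_x + stats::runif(1) * ext_x
      cy <- grid$origin_y - stats::runif(1) * ext_y
      s2 <- (stats::runif(1, 0.1, 0.4) * max(ext_x, ext_y))^2
      field <- field + exp(-((ctr$x - cx)^2 + (ctr$y - cy)^2) / (2 * s2))
    }
    q <- stats::quantile(field, c(0.2, 0.4, 0.6, 0.8), type = 1)
    cls <- findInterval(field, q, left.open = TRUE) + 1
    vals <- matrix(0, grid$n_rows, grid$n_cols)
    vals[cbind(ctr$row, ctr$col)] <- cls
    return(ugli_raster(grid, vals, nodata = -9999))
  }
  # flood: elevation grows with distance from a random corner, so the
  # sub-threshold (inundated) region is contiguous
  f <- if (is.null(params$inundated_fraction)) 0.3 else params$inundated_fraction
  if (f < 0 || f > 1) stop("inundated_fraction must lie in [0,1]", call. = FALSE)
  corner_x <- grid$origin_x + sample(c(0, grid$n_cols), 1L) * grid$pixel_size_x
  corner_y <- grid$origin_y - sample(c(0, grid$n_rows), 1L) * grid$pixel_size_y
  elev <- sqrt((ctr$x - corner_x)^2 + (ctr$y - corner_y)^2)
  if (f == 0) {
    wse_flat <- min(elev) - elev   # peaks at 0: nowhere strictly positive
  } else {
    thresh <- stats::quantile(elev, f, type = 1)
    wse_flat <- thresh - elev
  }
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  vals[cbind(ctr$row, ctr$col)] <- wse_flat
  ugli_raster(grid, vals, nodata = -9999)
}

#' Compare a population estimate against synthetic ground truth
#'
#' @param county A `synthetic_county`.
#' @param estimate A [population_raster()] on the county grid.
#' @return List with `max_abs_error`, `max_rel_error` (relative to truth
#'   where truth > 0), `support_mismatch_fraction` (share of pixels where
#'   exactly one of truth/estimate is nonzero), and `zone_residuals`
#'   (per-zone estimate total minus census population).
#' @export
recovery_report <- function(county, estimate) {
  stopifnot(inherits(county, "synthetic_county"),
            inherits(estimate, "ugli_raster"))
  stop_if_grid_mismatch(county$grid, estimate$grid,
                        "truth and estimate rasters")
  t_v <- county$truth$values
  e_v <- estimate$values
  e_v[is.na(e_v) | e_v == estimate$nodata] <- 0
  err <- e_v - t_v
  pos <- t_v > 0
  zidx <- rasterize_zones(county$zones, county$grid)
  agg <- aggregate_to_zones(estimate, zidx)
  res <- agg$total - county$zones$population[match(agg$zone_id, county$zones$zone_id)]
  list(max_abs_error = max(abs(err)),
       max_rel_error = if (any(pos)) max(abs(err[pos]) / t_v[pos]) else 0,
       support_mismatch_fraction = mean((t_v > 0) != (e_v > 0)),
       zone_residuals = data.frame(zone_id = agg$zone_id, residual = res,
                                   stringsAsFactors = FALSE))
}
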