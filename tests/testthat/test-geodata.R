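test_that("pixel centers follow the closed-form upper-left geotransform", {
  g <- grid_spec(1000, 5000, n_rows = 3, n_cols = 4,
                 pixel_size_x = 30, pixel_size_y = 30)
  expect_equal(as.vector(pixel_centers(g, 1, 1)), c(1015, 4985))
  expect_equal(as.vector(pixel_centers(g, 3, 4)),
               c(1000 + 3.5 * 30, 5000 - 2.5 * 30))
  expect_equal(pixel_area(g), 900)
  expect_error(grid_spec(0, 0, 2, 2, pixel_size_x = -1), "positive")
})

test_that("ASCII grid write-then-read round-trips values and grid exactly", {
  g <- grid_spec(12345.6789, 987654.321, n_rows = 5, n_cols = 7,
                 crs_id = "EPSG:5070")
  set.seed(42)
  vals <- matrix(runif(35), 5, 7)
  vals[2, 3] <- -9999  # nodata pixel
  r <- ugli_raster(g, vals)
  path <- file.path(withr::local_tempdir(), "r.asc")
  write_ascii_raster(r, path)
  r2 <- read_ascii_raster(path)
  expect_identical(r2$values, r$values)    # bit-compatible
  expect_equal(r2$grid, r$grid)
  expect_equal(r2$nodata, r$nodata)
})

test_that("a raster without a CRS sidecar is refused as unprojected", {
  g <- test_grid(2, 2)
  path <- file.path(withr::local_tempdir(), "imp.asc")
  write_ascii_raster(impervious_raster(g, matrix(0.5, 2, 2)), path)
  file.remove(sub("asc$", "prj", path))
  expect_error(read_impervious_raster(path, "fraction_0_1"), "unprojected")
})

test_that("impervious reader rescales percent to fraction and zeroes nodata", {
  g <- test_grid(3, 3)
  vals <- matrix(c(100, 0, 50, 25, -9999, 1, 0, 0, 75), 3, 3, byrow = TRUE)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "imp.asc")
  write_ascii_raster(ugli_raster(g, vals), path)
  imp <- read_impervious_raster(path, "percent_0_100")
  expect_equal(imp$values[1, 1], 1.0)   # 100% -> 1
  expect_equal(imp$values[1, 2], 0.0)   # 0% -> 0
  expect_equal(imp$values[2, 2], 0.0)   # nodata -> uninhabitable
  expect_identical(attr(imp, "nodata_count"), sum(vals == -9999))
  # fraction dialect with out-of-range values is refused with the range
  path2 <- file.path(dir, "bad.asc")
  write_ascii_raster(ugli_raster(g, matrix(50, 3, 3)), path2)
  expect_error(read_impervious_raster(path2, "fraction_0_1"),
               "outside declared scale")
})

test_that("rasterization labels pixels by zone containing the centre", {
  g <- test_grid(4, 4)
  # total cover by one zone
  one <- zone_set("00-001-A", 10, list(pix_rect(g, 1, 4, 1, 4)),
                  crs_id = g$crs_id)
  zidx <- rasterize_zones(one, g)
  expect_true(all(zidx$values == 1L))
  # a centre 1 m outside all zones gets the NONE sentinel
  small <- zone_set("00-001-A", 10, list(pix_rect(g, 1, 4, 1, 3)),
                    crs_id = g$crs_id)
  zidx2 <- rasterize_zones(small, g)
  expect_true(all(is.na(zidx2$values[, 4])))
  expect_true(all(zidx2$values[, 1:3] == 1L))
  expect_error(rasterize_zones(one, test_grid(4, 4, crs = "EPSG:9999")),
               "CRS")
})

test_that("boundary ties go to the lexicographically smaller zone id", {
  g <- test_grid(4, 4)
  # vertical split exactly through the pixel centres of column 2
  xsplit <- g$origin_x + 1.5 * g$pixel_size_x
  left <- matrix(c(0, 0, xsplit, 0, xsplit, 120, 0, 120), ncol = 2, byrow = TRUE)
  right <- matrix(c(xsplit, 0, 120, 0, 120, 120, xsplit, 120), ncol = 2, byrow = TRUE)
  zones <- zone_set(c("00-001-B", "00-001-A"), c(1, 1), list(left, right),
                    crs_id = g$crs_id)
  zidx <- rasterize_zones(zones, g)
  got <- index_to_ids(zidx)
  expect_equal(got, oracle_rasterize(zones, g))
  # column-2 centres lie on the shared edge of A (right) and B (left):
  # the lexicographically smaller id wins
  expect_true(all(got[, 2] == "00-001-A"))
  expect_true(all(got[, 1] == "00-001-B"))
  expect_true(all(got[, 3:4] == "00-001-A"))
})

test_that("rasterization agrees with the point-in-polygon oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- test_grid(sample(3:8, 1), sample(3:8, 1))
    n <- sample(2:4, 1)
    zones <- strip_zones(g, n_strips = if (g$n_cols %% n == 0) n else 1)
    got <- index_to_ids(rasterize_zones(zones, g))
    expect_equal(got, oracle_rasterize(zones, g))
  }
})

test_that("clipping crops to the zone bbox and never alters retained pixels", {
  g <- test_grid(2, 4)
  vals <- matrix(1:8, 2, 4)
  r <- ugli_raster(g, vals)
  # full cover: identity
  full <- zone_set("z", 1, list(pix_rect(g, 1, 2, 1, 4)), crs_id = g$crs_id)
  expect_equal(clip_to_county(r, full)$values, r$values)
  expect_equal(clip_to_county(r, full)$grid, r$grid)
  # left half: crop to 2x2, values untouched
  half <- zone_set("z", 1, list(pix_rect(g, 1, 2, 1, 2)), crs_id = g$crs_id)
  cl <- clip_to_county(r, half)
  expect_equal(cl$grid$n_cols, 2L)
  expect_equal(cl$grid$n_rows, 2L)
  expect_equal(cl$values, vals[, 1:2])
  # idempotence
  expect_equal(clip_to_county(cl, half)$values, cl$values)
  # zero overlap is an error
  far <- zone_set("z", 1,
                  list(matrix(c(1e6, 0, 1e6 + 30, 0, 1e6 + 30, 30, 1e6, 30),
                              ncol = 2, byrow = TRUE)), crs_id = g$crs_id)
  expect_error(clip_to_county(r, far), "overlap")
})

test_that("clipping nodata-fills pixels whose centre leaves the union", {
  g <- test_grid(2, 4)
  r <- ugli_raster(g, matrix(5, 2, 4))
  # zone covers x in [0, 40]: column-2 centres (x = 45) are outside, but
  # the snapped crop still spans two columns
  geom <- matrix(c(0, 0, 40, 0, 40, 60, 0, 60), ncol = 2, byrow = TRUE)
  z <- zone_set("z", 1, list(geom), crs_id = g$crs_id)
  cl <- clip_to_county(r, z)
  expect_equal(cl$grid$n_cols, 2L)
  expect_true(all(cl$values[, 1] == 5))
  expect_true(all(cl$values[, 2] == cl$nodata))
})

test_that("county-code harmonization renames, merges, and conserves population", {
  g <- test_grid(2, 2)
  geoms <- list(pix_rect(g, 1, 1, 1, 1), pix_rect(g, 1, 1, 2, 2),
                pix_rect(g, 2, 2, 1, 1))
  blocks <- zone_set(c("46-113-B001", "46-113-B002", "51-515-B001"),
                     c(40, 60, 25), geoms, crs_id = g$crs_id)
  # empty map: identity
  expect_identical(harmonize_county_codes(blocks, county_code_map()), blocks)
  out <- harmonize_county_codes(blocks, default_county_code_map())
  expect_equal(substr(out$zone_id, 1, 6), c("46-102", "46-102", "51-019"))
  expect_identical(out$population, blocks$population)  # record-by-record
  expect_equal(sum(out$population), sum(blocks$population))
  # idempotent
  expect_identical(harmonize_county_codes(out, default_county_code_map()), out)
  # merge semantics: all members re-parented, total preserved
  m <- county_code_map(merges = list(list(members = c("10-001", "10-002"),
                                          survivor = "10-002")))
  b2 <- zone_set(c("10-001-B1", "10-002-B2"), c(40, 60),
                 geoms[1:2], crs_id = g$crs_id)
  out2 <- harmonize_county_codes(b2, m)
  expect_true(all(startsWith(out2$zone_id, "10-002")))
  expect_equal(sum(out2$population), 100)
  # rename onto an existing distinct county is refused
  bad <- county_code_map(renames = data.frame(old = "10-001", new = "10-002"))
  expect_error(harmonize_county_codes(b2, bad), "collides")
  # a code cannot be both rename source and merge member
  expect_error(county_code_map(renames = data.frame(old = "10-001", new = "10-003"),
                               merges = list(list(members = "10-001",
                                                  survivor = "10-009"))),
               "both")
})

test_that("population raster writer embeds the county code and round-trips", {
  g <- test_grid(3, 3)
  vals <- matrix(runif(9), 3, 3)
  vals[2, 2] <- -9999
  pop <- population_raster(g, ifelse(vals == -9999, -9999, abs(vals)))
  dir <- withr::local_tempdir()
  path <- write_population_raster(pop, dir, "24-003")
  expect_match(basename(path), "24-003", fixed = TRUE)
  r2 <- read_ascii_raster(path)
  expect_identical(r2$values, pop$values)
  expect_equal(r2$values[2, 2], r2$nodata)  # nodata survives round-trip
  expect_equal(r2$grid, g)
  expect_error(write_population_raster(pop, dir, "24003"), "county code")
})

test_that("zone sets validate ids, populations and geometry", {
  g <- test_grid(2, 2)
  geom <- pix_rect(g, 1, 2, 1, 2)
  expect_error(zone_set(c("a", "a"), c(1, 1), list(geom, geom)), "unique")
  expect_error(zone_set("a", -5, list(geom)), "non-negative")
  z <- zone_set("a", 3, list(geom), crs_id = g$crs_id)
  path <- file.path(withr::local_tempdir(), "z.geojson")
  write_zones_geojson(z, path)
  z2 <- read_zones_geojson(path, crs_id = g$crs_id)
  expect_equal(z2$zone_id, z$zone_id)
  expect_equal(z2$population, z$population)
  expect_equal(geometry_area(z2$geometry[[1]]), geometry_area(z$geometry[[1]]))
})
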