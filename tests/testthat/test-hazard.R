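test_that("wildfire binarization maps medium/high/very-high to at risk", {
  g <- test_grid(1, 5)
  whp <- ugli_raster(g, matrix(1:5, 1, 5))
  b <- binarize_wildfire(whp)
  expect_equal(as.vector(b$values), c(0, 0, 1, 1, 1))  # classes 3-5 at risk
  # total class set marks every valid pixel
  expect_true(all(binarize_wildfire(whp, at_risk_classes = 1:5)$values == 1))
  # a stray code outside the legend is refused by name
  bad <- ugli_raster(g, matrix(c(1, 2, 3, 9, 5), 1, 5))
  expect_error(binarize_wildfire(bad), "9")
  # nodata pixels are never at risk
  nd <- ugli_raster(g, matrix(c(5, -9999, 5, 5, 5), 1, 5))
  expect_equal(as.vector(binarize_wildfire(nd)$values), c(1, 0, 1, 1, 1))
})

test_that("flood binarization is strictly positive water surface elevation", {
  g <- test_grid(1, 4)
  wse <- ugli_raster(g, matrix(c(0, 0.3, -2, 1e-12), 1, 4))
  b <- binarize_flood(wse)
  expect_equal(as.vector(b$values), c(0, 1, 0, 1))
  allneg <- ugli_raster(g, matrix(-abs(rnorm(4)), 1, 4))
  expect_true(all(binarize_flood(allneg)$values == 0))
})

test_that("polygonize merges adjacent pixels; areas equal pixel count x 900", {
  g <- test_grid(3, 3)
  v <- matrix(0, 3, 3); v[2, 2] <- 1
  mask <- binarize_flood(ugli_raster(g, v))
  polys <- polygonize_binary(mask)
  one <- polys[polys$at_risk, ]
  expect_equal(nrow(one), 1L)
  expect_equal(one$area, 900)            # single 30-m pixel
  expect_equal(one$n_pixels, 1L)
  # traced geometry area agrees with the pixel count
  geom <- attr(polys, "geometry")[[which(polys$at_risk)]]
  expect_equal(geometry_area(geom), 900)
  # an all-true raster is one polygon covering the grid
  all1 <- binarize_flood(ugli_raster(g, matrix(1, 3, 3)))
  p1 <- polygonize_binary(all1)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$area, 9 * 900)
  expect_equal(geometry_area(attr(p1, "geometry")[[1]]), 9 * 900)
})

test_that("checkerboard splits under 4-connectivity and merges under 8", {
  g <- test_grid(2, 2)
  v <- matrix(c(1, 0, 0, 1), 2, 2)
  mask <- binarize_flood(ugli_raster(g, v))
  p4 <- polygonize_binary(mask, connectivity = 4)
  expect_equal(sum(p4$at_risk), 2L)
  p8 <- polygonize_binary(mask, connectivity = 8)
  expect_equal(sum(p8$at_risk), 1L)
  expect_error(polygonize_binary(mask, connectivity = 6), "4 or 8")
})

test_that("component counts agree with a flood-fill oracle; holes traced", {
  for (seed in 1:8) {
    set.seed(seed)
    g <- test_grid(9, 9)
    v <- matrix(rbinom(81, 1, 0.45), 9, 9)
    mask <- binarize_flood(ugli_raster(g, v))
    for (conn in c(4, 8)) {
      polys <- polygonize_binary(mask, connectivity = conn)
      expect_equal(nrow(polys), oracle_component_count(v, conn))
      # per-polygon traced area always equals pixel count x pixel area
      areas <- vapply(attr(polys, "geometry"), geometry_area, numeric(1))
      expect_equal(areas, polys$n_pixels * 900)
    }
  }
  # explicit hole: ring of risk around a dry pixel
  g <- test_grid(3, 3)
  v <- matrix(1, 3, 3); v[2, 2] <- 0
  polys <- polygonize_binary(binarize_flood(ugli_raster(g, v)))
  ringpoly <- attr(polys, "geometry")[[which(polys$at_risk)]]
  expect_equal(geometry_area(ringpoly), 8 * 900)
  expect_equal(length(ringpoly[[1]]), 2L)  # shell + hole
})

test_that("zonal sums match masked-array sums and partition the total", {
  set.seed(14)
  g <- test_grid(10, 10)
  pv <- matrix(rexp(100, 1 / 5), 10, 10)
  pop <- population_raster(g, pv)
  v <- matrix(rbinom(100, 1, 0.4), 10, 10)
  polys <- polygonize_binary(binarize_flood(ugli_raster(g, v)))
  zs <- zonal_population_sum(pop, polys)
  expect_equal(zs$at_risk_total, sum(pv[v == 1]))
  expect_equal(zs$not_at_risk_total, sum(pv[v == 0]))
  expect_equal(zs$at_risk_total + zs$not_at_risk_total, sum(pv))
  # polygon covering the whole raster returns the raster sum
  all1 <- polygonize_binary(binarize_flood(ugli_raster(g, matrix(1, 10, 10))))
  expect_equal(zonal_population_sum(pop, all1)$grand_total, sum(pv))
  # per-polygon sums equal direct masked sums
  per <- zonal_population_sum(pop, polys)$per_polygon
  pix <- attr(polys, "pixels")
  for (i in seq_len(nrow(per))) {
    expect_equal(per$population[i], sum(pv[pix[[i]]]))
  }
})

test_that("zonal sums overlay rasters on a different native grid", {
  # population at half the hazard resolution (60 m pixels)
  hz_grid <- test_grid(4, 4)
  pop_grid <- grid_spec(0, 120, n_rows = 2, n_cols = 2,
                        pixel_size_x = 60, pixel_size_y = 60,
                        crs_id = hz_grid$crs_id)
  pv <- matrix(c(10, 20, 30, 40), 2, 2)
  pop <- population_raster(pop_grid, pv)
  v <- matrix(0, 4, 4); v[1:2, 1:2] <- 1   # risk = NW quadrant
  polys <- polygonize_binary(binarize_flood(ugli_raster(hz_grid, v)))
  zs <- zonal_population_sum(pop, polys)
  expect_equal(zs$at_risk_total, 10)  # only the NW 60-m cell centre is inside
})

test_that("areal weighting multiplies population by overlap proportion", {
  g <- test_grid(4, 4)
  v <- matrix(0, 4, 4); v[1:2, 1:2] <- 1
  polys <- polygonize_binary(binarize_flood(ugli_raster(g, v)))
  # zone fully inside the risk region contributes all its population
  zin <- zone_set("zin", 80, list(pix_rect(g, 1, 2, 1, 2)), crs_id = g$crs_id)
  expect_equal(areal_weighting_exposure(zin, polys), 80)
  # whole-grid zone: 25% overlap -> 25% of population
  zall <- zone_set("zall", 100, list(pix_rect(g, 1, 4, 1, 4)), crs_id = g$crs_id)
  expect_equal(areal_weighting_exposure(zall, polys), 25)
  # disjoint zone contributes nothing
  zout <- zone_set("zout", 100, list(pix_rect(g, 3, 4, 3, 4)), crs_id = g$crs_id)
  expect_equal(areal_weighting_exposure(zout, polys), 0)
  # zero-area zone with population is an error
  degenerate <- zone_set("bad", 5,
                         list(matrix(c(0, 0, 30, 0, 60, 0), ncol = 2,
                                     byrow = TRUE)), crs_id = g$crs_id)
  expect_error(areal_weighting_exposure(degenerate, polys), "zero area")
})

test_that("population at risk is monotone under risk-region growth", {
  set.seed(31)
  g <- test_grid(10, 10)
  pv <- matrix(rexp(100), 10, 10)
  pop <- population_raster(g, pv)
  zones <- strip_zones(g, 2, populations = c(100, 200))
  v1 <- matrix(0, 10, 10); v1[3:5, 3:5] <- 1
  v2 <- v1; v2[3:8, 3:8] <- 1            # superset region
  p1 <- polygonize_binary(binarize_flood(ugli_raster(g, v1)))
  p2 <- polygonize_binary(binarize_flood(ugli_raster(g, v2)))
  expect_gte(zonal_population_sum(pop, p2)$at_risk_total,
             zonal_population_sum(pop, p1)$at_risk_total)
  expect_gte(areal_weighting_exposure(zones, p2),
             areal_weighting_exposure(zones, p1))
})

test_that("uniform population and pixel-aligned zones make the two methods agree", {
  g <- test_grid(8, 8)
  zones <- strip_zones(g, 2, populations = c(320, 640))
  zidx <- rasterize_zones(zones, g)
  # exactly uniform population over each zone's pixels
  pv <- matrix(0, 8, 8)
  for (k in 1:2) pv[zidx$values == k] <- zones$population[k] / sum(zidx$values == k)
  pop <- population_raster(g, pv)
  v <- matrix(0, 8, 8); v[2:5, ] <- 1    # axis-aligned risk rectangle
  polys <- polygonize_binary(binarize_flood(ugli_raster(g, v)))
  zonal <- zonal_population_sum(pop, polys)$at_risk_total
  areal <- areal_weighting_exposure(zones, polys)
  expect_equal(zonal, areal, tolerance = 1e-12)
})

test_that("percent difference is the relative departure from the baseline", {
  expect_equal(percent_difference(100, 100), 0)
  expect_equal(percent_difference(80, 100), -20)
  expect_equal(percent_difference(0, 100), -100)
  expect_error(percent_difference(5, 0), "undefined")
})
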