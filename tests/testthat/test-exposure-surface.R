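# Unit conversion, variography, kriging, population disaggregation,
# overlay and population-weighted exposure.

test_that("TSP to PM10 conversion applies the fixed factor", {
  expect_equal(tsp_to_pm10(600), 330)
  expect_equal(tsp_to_pm10(0), 0)
  expect_equal(tsp_to_pm10(1000), 550)
  expect_equal(tsp_to_pm10(c(600, 1000)), c(330, 550))
  expect_error(tsp_to_pm10(-1), "non-negative")
})

test_that("variogram models respect their invariants", {
  v <- fit_variogram(default_chain$stations[, c("lon", "lat")],
                     default_chain$station_pm10, "spherical")
  expect_gt(v$range, 0)
  expect_gte(v$sill, v$nugget)
  expect_error(variogram_model("spherical", nugget = 2, sill = 1, range = 1),
               "sill")
  expect_error(fit_variogram(cbind(0:1, 0:1), c(1, 2)), "at least 3")
  # identical values degenerate with a warning, and krige to a constant
  co <- data.frame(lon = c(0, 0.1, 0.05), lat = c(0, 0, 0.1))
  expect_warning(vd <- fit_variogram(co, c(330, 330, 330)), "degenerate")
  kr <- krige_points(co, c(330, 330, 330), vd,
                     data.frame(lon = runif(5, 0, 0.1),
                                lat = runif(5, 0, 0.1)))
  expect_equal(kr$values, rep(330, 5), tolerance = 1e-9)
})

test_that("a known spherical variogram is recovered from a sampled field", {
  set.seed(99)
  n <- 50
  pts <- cbind(runif(n, 0, 0.2), runif(n, 0, 0.2))
  truth <- variogram_model("spherical", nugget = 0, sill = 1, range = 0.05)
  cm <- 1 - vgm_gamma(truth, airhia:::dist_deg(pts))
  diag(cm) <- 1 + 1e-8
  field <- as.numeric(t(chol(cm)) %*% rnorm(n))
  fit <- fit_variogram(pts, field, "spherical")
  expect_lt(abs(fit$range - 0.05) / 0.05, 0.30)
})

test_that("ordinary kriging is exact at stations and weights sum to one", {
  ch <- default_chain
  kr <- krige_points(ch$stations[, c("lon", "lat")], ch$station_pm10,
                     ch$vgm, ch$stations[, c("lon", "lat")])
  expect_equal(kr$values, ch$station_pm10, tolerance = 1e-6)
  set.seed(4)
  pts <- data.frame(lon = runif(100, 103.5, 103.95),
                    lat = runif(100, 35.98, 36.13))
  kr2 <- krige_points(ch$stations[, c("lon", "lat")], ch$station_pm10,
                      ch$vgm, pts)
  expect_true(all(abs(colSums(kr2$weights) - 1) < 1e-8))
})

test_that("kriging a constant field returns the constant everywhere", {
  co <- default_chain$stations[, c("lon", "lat")]
  v <- variogram_model("exponential", 0, 100, 0.1)
  g <- grid_spec(103.5, 35.98, 0.05, 9, 3)
  surf <- krige_surface(default_chain$stations, rep(330, nrow(co)), g, v)
  expect_equal(as.numeric(surf$values), rep(330, 27), tolerance = 1e-9)
})

test_that("two equidistant stations get equal weights at the midpoint", {
  v <- variogram_model("spherical", 0, 1, 0.1)
  co <- data.frame(lon = c(0, 0.04), lat = c(0, 0))
  kr <- krige_points(co, c(10, 20), v, data.frame(lon = 0.02, lat = 0))
  expect_equal(as.numeric(kr$weights), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(kr$values, 15, tolerance = 1e-10)
})

test_that("duplicate stations are rejected as a singular system", {
  v <- variogram_model("spherical", 0, 1, 0.1)
  co <- data.frame(lon = c(0, 0), lat = c(0, 0))
  expect_error(krige_points(co, c(1, 2), v, data.frame(lon = 1, lat = 1)),
               "singular")
})

test_that("population disaggregation is mass-preserving", {
  # identity when grids coincide
  g <- grid_spec(0, 0, 0.02, 4, 4)
  src <- new_raster(g, matrix(runif(16, 0, 100), 4, 4))
  out <- interpolate_population(src, g)
  expect_equal(out$values, src$values, tolerance = 1e-12)
  # one coarse cell splits uniformly into four fine cells
  g1 <- grid_spec(0, 0, 0.02, 1, 1)
  gf <- grid_spec(0, 0, 0.01, 2, 2)
  fine <- interpolate_population(new_raster(g1, matrix(1000, 1, 1)), gf)
  expect_equal(as.numeric(fine$values), rep(250, 4))
  # arbitrary overlapping grids conserve the total
  gs <- grid_spec(0.003, 0.007, 0.017, 7, 5)
  src2 <- new_raster(gs, matrix(rexp(35, 1 / 50), 5, 7))
  gt <- grid_spec(0, 0, 0.01, 13, 10)   # covers the source extent
  out2 <- interpolate_population(src2, gt)
  expect_equal(sum(out2$values), sum(src2$values), tolerance = 1e-3)
  # disjoint extents are rejected
  expect_error(interpolate_population(src2, grid_spec(10, 10, 0.01, 5, 5)),
               "disjoint")
})

test_that("overlay keeps populated cells with valid concentrations", {
  g <- grid_spec(0, 0, 0.01, 5, 4)
  conc <- new_raster(g, matrix(300 + 1:20, 4, 5))
  pop0 <- new_raster(g, matrix(0, 4, 5))
  expect_equal(nrow(overlay(conc, pop0)), 0)
  # NODATA concentration cells with population are dropped and counted
  cv <- matrix(300 + 1:20, 4, 5)
  cv[2, 3] <- NA
  pv <- matrix(10, 4, 5)
  tab <- overlay(new_raster(g, cv), new_raster(g, pv))
  expect_equal(nrow(tab), 19)
  expect_equal(attr(tab, "n_dropped_nodata"), 1)
  # grid mismatch is rejected
  expect_error(overlay(conc, new_raster(grid_spec(0, 0, 0.02, 5, 4), 1)),
               "co-registered")
})

test_that("an exposure scene with 475 populated cells yields 475 rows", {
  g <- default_scene$population$grid
  set.seed(8)
  pv <- matrix(0, g$nrows, g$ncols)
  pv[sample(length(pv), 475)] <- runif(475, 100, 5000)
  tab <- overlay(default_chain$surface, new_raster(g, pv))
  expect_equal(nrow(tab), 475)
})

test_that("population-weighted exposure is the population-weighted mean", {
  t1 <- data.frame(population = c(1, 1), pm10_ugm3 = c(300, 400))
  expect_equal(population_weighted_exposure(t1), 350)
  t2 <- data.frame(population = c(3, 1), pm10_ugm3 = c(300, 400))
  expect_equal(population_weighted_exposure(t2), 325)
  # convex-combination bound and the uniform-population identity
  tab <- default_chain$table
  pwel <- population_weighted_exposure(tab)
  expect_gte(pwel, min(tab$pm10_ugm3))
  expect_lte(pwel, max(tab$pm10_ugm3))
  uni <- tab
  uni$population <- 1
  expect_equal(population_weighted_exposure(uni), mean(tab$pm10_ugm3))
  expect_error(population_weighted_exposure(
    data.frame(population = 0, pm10_ugm3 = 1)), "positive")
})

test_that("exposure distribution uses left-closed bins and conserves people", {
  tab <- data.frame(population = c(5, 10, 20, 40),
                    pm10_ugm3 = c(290, 310, 350, 400))
  counts <- exposure_distribution(tab, c(280, 310, 340, 370, 410))
  expect_equal(as.numeric(counts), c(5, 10, 20, 40))
  # 310 sits exactly on an interior edge -> right-hand bin
  expect_equal(as.numeric(counts[2]), 10)
  # a value on the last edge is included (closed last bin)
  tab2 <- data.frame(population = 7, pm10_ugm3 = 410)
  expect_equal(as.numeric(exposure_distribution(tab2, c(280, 345, 410))),
               c(0, 7))
  expect_error(exposure_distribution(tab, c(300, 350, 420)),
               "do not cover")
  expect_error(exposure_distribution(tab, c(280, 280, 410)), "increasing")
  # brute-force oracle on the default scene
  edges <- seq(min(default_chain$table$pm10_ugm3) - 1,
               max(default_chain$table$pm10_ugm3) + 1, length.out = 6)
  got <- exposure_distribution(default_chain$table, edges)
  brute <- vapply(seq_len(5), function(j) {
    x <- default_chain$table
    last <- j == 5
    sel <- x$pm10_ugm3 >= edges[j] &
      (if (last) x$pm10_ugm3 <= edges[j + 1] else x$pm10_ugm3 < edges[j + 1])
    sum(x$population[sel])
  }, numeric(1))
  expect_equal(as.numeric(got), brute)
  expect_equal(sum(got), sum(default_chain$table$population))
})

test_that("station correlation is standard Pearson with guards", {
  x <- c(1, 2, 3, 5, 4)
  expect_equal(station_correlation(x, x), 1)
  expect_equal(station_correlation(x, -x), -1)
  expect_equal(station_correlation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_error(station_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(station_correlation(c(1, NA, 3, NA), c(1, 2, 3, 4)),
               "at least 3")
  # the default network is internally consistent: every station correlates
  # highly with the first (the representativeness check)
  tsp <- default_scene$tsp
  wide <- matrix(tsp$tsp_ugm3, ncol = nrow(default_chain$stations))
  r <- vapply(2:ncol(wide),
              function(j) station_correlation(wide[, 1], wide[, j]),
              numeric(1))
  expect_true(all(r >= 0.8))
})

test_that("ASCII grid round-trips through write and read", {
  g <- grid_spec(103.5, 35.98, 0.01, 6, 4)
  vals <- matrix(runif(24, 100, 500), 4, 6)
  vals[2, 2] <- NA
  r <- new_raster(g, vals, units = "ug/m3")
  p <- withr::local_tempfile(fileext = ".asc")
  write_asc(r, p)
  rr <- read_asc(p, units = "ug/m3")
  expect_equal(rr$values, r$values, tolerance = 1e-8)
  expect_true(same_grid <- airhia:::same_grid(rr$grid, r$grid))
})

test_that("GeoJSON stations round-trip", {
  st <- default_chain$stations
  p <- withr::local_tempfile(fileext = ".geojson")
  write_stations_geojson(st, p)
  back <- read_stations_geojson(p)
  expect_equal(back$station_id, st$station_id)
  expect_equal(back$lon, st$lon)
  expect_equal(back$lat, st$lat)
})

test_that("mg-unit concentration files read identically to ug files", {
  tsp <- head(default_scene$tsp, 50)
  p_ug <- withr::local_tempfile(fileext = ".csv")
  p_mg <- withr::local_tempfile(fileext = ".csv")
  airhia:::write_csv_plain(tsp, p_ug)
  tsp_mg <- transform(tsp, tsp_ugm3 = tsp_ugm3 / 1000)
  airhia:::write_csv_plain(tsp_mg, p_mg)
  a <- read_tsp_csv(p_ug, unit = "ug")
  b <- read_tsp_csv(p_mg, unit = "mg")
  expect_equal(a$tsp_ugm3, b$tsp_ugm3, tolerance = 1e-12)
})
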