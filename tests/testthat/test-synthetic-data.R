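# The generator must be deterministic, respect its declared invariants
# (mass conservation, ordering of weather variables, the configured
# seasonal shape) and produce data whose statistical structure matches the
# documented data-generating process.

test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(domain_bounds = c(103.5, 36, 103.5, 36.2)),
               "positive width")
  expect_error(sim_config(n_stations = 2), "n_stations")
  expect_error(sim_config(baseline_rate = 0), "baseline_rate")
  expect_error(sim_config(resolution = -0.01), "resolution")
  expect_error(sim_config(total_population = -5), "total_population")
})

test_that("station network is reproducible, in-bounds and non-colocated", {
  cfg <- sim_config(seed = 42, n_stations = 7)
  a <- generate_station_network(cfg)
  b <- generate_station_network(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 7)
  bd <- cfg$domain_bounds
  expect_true(all(a$lon > bd[1] & a$lon < bd[3]))
  expect_true(all(a$lat > bd[2] & a$lat < bd[4]))
  d <- as.matrix(dist(a[, c("lon", "lat")]))
  expect_gt(min(d[upper.tri(d)]), 1e-4)
  # a different seed moves the stations
  expect_false(identical(a, generate_station_network(sim_config(seed = 43))))
})

test_that("TSP series has the configured annual cycle and correlation", {
  tsp <- default_scene$tsp
  pm <- tsp_to_pm10(tsp$tsp_ugm3)
  monthly <- tapply(pm, format(tsp$date, "%m"), mean)
  top2 <- names(sort(monthly, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("04", "12"))
  expect_equal(names(which.min(monthly)), "08")
  expect_true(all(tsp$tsp_ugm3 > 0))
  wide <- matrix(tsp$tsp_ugm3, ncol = length(unique(tsp$station_id)))
  cm <- cor(wide)
  expect_true(all(cm[upper.tri(cm)] >= 0.8))
})

test_that("seasonal peak months dominate across seeds", {
  hits <- vapply(2:6, function(s) {
    cfg <- sim_config(seed = s)
    tsp <- generate_tsp_series(cfg, generate_station_network(cfg))
    monthly <- tapply(tsp$tsp_ugm3, format(tsp$date, "%m"), mean)
    setequal(names(sort(monthly, decreasing = TRUE))[1:2], c("04", "12")) &&
      names(which.min(monthly)) == "08"
  }, logical(1))
  expect_true(all(hits))
})

test_that("zero idiosyncratic noise makes stations scaled copies", {
  cfg <- sim_config(seed = 3, noise_sd = 0)
  st <- generate_station_network(cfg)
  tsp <- generate_tsp_series(cfg, st)
  wide <- matrix(tsp$tsp_ugm3, ncol = nrow(st))
  cm <- cor(wide)
  expect_equal(max(abs(cm - 1)), 0, tolerance = 1e-12)
})

test_that("population raster conserves mass and spans the stated densities", {
  pop <- default_scene$population
  cfg <- default_config
  expect_equal(sum(pop$values), cfg$total_population,
               tolerance = 1e-3)
  area <- matrix(cell_area_km2(pop$grid), pop$grid$nrows, pop$grid$ncols)
  dens <- pop$values / area
  expect_gt(max(dens), 3700)
  # belt interior: cells within half a belt width of the axis
  cc <- cell_centers(pop$grid)
  dperp <- outer(cc$lat, cc$lon,
                 function(la, lo) airhia:::belt_distance(cfg, lo, la))
  expect_true(all(dens[dperp < cfg$belt_width / 2] >= 800))
  expect_error(generate_population_raster(sim_config(total_population = -1)),
               "total_population")
})

test_that("a vanishing belt width concentrates all mass on the ridge", {
  cfg <- sim_config(seed = 2, belt_width = 1e-4)
  pop <- generate_population_raster(cfg)
  cc <- cell_centers(pop$grid)
  dperp <- outer(cc$lat, cc$lon,
                 function(la, lo) airhia:::belt_distance(cfg, lo, la))
  ridge <- dperp < cfg$resolution
  expect_gt(sum(pop$values[ridge]) / sum(pop$values), 0.999)
})

test_that("weather confounders are ordered, seasonal and reproducible", {
  conf <- default_scene$confounders
  expect_true(all(conf$t_min <= conf$t_mean))
  expect_true(all(conf$t_mean <= conf$t_max))
  expect_identical(conf, generate_confounders(default_config))
  # summer warmer than winter
  mo <- format(conf$date, "%m")
  expect_gt(mean(conf$t_mean[mo == "07"]), mean(conf$t_mean[mo == "01"]))
  flat <- generate_confounders(sim_config(seed = 5, weather_amplitude = 0))
  expect_equal(var(flat$t_mean), 0)
  expect_equal(var(flat$pressure_hpa), 0)
})

test_that("admissions follow the stored log-mean function", {
  scene <- default_scene
  cfg <- default_config
  truth <- scene$truth
  # independent recomputation of the log-mean from the declared DGP
  n <- nrow(scene$confounders)
  keep <- (cfg$lag_true + 1):n
  pm_lag <- scene$pm10_fit$pm10_ugm3[keep - cfg$lag_true]
  dat <- scene$confounders[keep, ]
  tt <- seq_along(keep)
  u <- (tt - length(tt) / 2) / (length(tt) / 2)
  dow <- c(Mon = 0, Tue = 0.01, Wed = 0.02, Thu = 0, Fri = 0.03,
           Sat = -0.08, Sun = -0.12)
  log_mu <- log(cfg$baseline_rate) +
    dow[as.integer(format(dat$date, "%u"))] +
    cfg$beta_true * (pm_lag - cfg$annual_mean_pm10) +
    0.10 * u - 0.06 * u^2 +
    0.010 * (dat$t_max - 15) + 0.0002 * (dat$t_max - 15)^2
  expect_equal(as.numeric(log_mu), truth$log_mu, tolerance = 1e-12)
  # the realisation is consistent with its mean function
  expect_equal(mean(scene$admissions$admissions), mean(exp(truth$log_mu)),
               tolerance = 0.02)
})

test_that("a concentration shift multiplies the mean by exp(beta * dC)", {
  cfg <- sim_config(seed = 9, beta_true = 2e-4, lag_true = 4)
  conf <- generate_confounders(cfg, years = 2001)
  base <- rep(300, nrow(conf))
  a <- generate_admissions(base, conf, cfg)
  b <- generate_admissions(base + 50, conf, cfg)
  fold <- exp(b$truth$log_mu - a$truth$log_mu)
  expect_equal(fold, rep(exp(2e-4 * 50), length(fold)), tolerance = 1e-12)
})

test_that("with all effects off the counts are plain Poisson(10)", {
  cfg <- sim_config(seed = 11, beta_true = 0, baseline_rate = 10,
                    weather_amplitude = 0)
  conf <- generate_confounders(cfg, years = 2001)
  # flatten the remaining structure: constant exposure kills the beta term,
  # zero weather amplitude kills the weather smooth
  adm <- generate_admissions(rep(cfg$annual_mean_pm10, nrow(conf)), conf, cfg)
  mu <- exp(adm$truth$log_mu)
  m <- mean(adm$data$admissions)
  expect_lt(abs(m - mean(mu)), 3 * sqrt(10 / 365))
  expect_true(all(adm$data$admissions == floor(adm$data$admissions)))
})

test_that("too-short exposure series is rejected", {
  cfg <- sim_config(seed = 1, lag_true = 4)
  conf <- generate_confounders(cfg, years = 2001)[1:4, ]
  expect_error(generate_admissions(rep(300, 4), conf, cfg), "lag_true")
})

test_that("identical config and seed give byte-identical written scenes", {
  cfg <- sim_config(seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_scene(generate_scene(cfg), d1)
  p2 <- write_scene(generate_scene(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
})

test_that("null exposure effect is not detected spuriously", {
  # with beta_true = 0 the fitted 95% CI should cover 0 at close to the
  # nominal rate
  cover <- vapply(1:50, function(s) {
    adm <- make_fit_dataset(s, beta_true = 0)
    f <- fit_poisson_gam(build_design(adm$data, lag = 4, default_smooths))
    f$ci95[1] <= 0 && f$ci95[2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.87)
})
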