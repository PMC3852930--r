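# Synthetic scene generator. Emulates the study design the pipeline is
# built for: a small monitoring network over a narrow rectangular urban
# belt, a pollutant with spring and winter peaks and a summer minimum, a
# belt-shaped population surface, and daily respiratory admissions driven
# by a known log-linear exposure effect at a known lag — so every
# downstream stage can be tested against a retrievable truth.

#' Configuration for the synthetic scene
#'
#' Defaults describe a Lanzhou-like urban valley: a ~45 x 15 km domain, a
#' seven-station network, TSP averaging about 600 ug/m^3 (330 ug/m^3 as
#' PM10) with April and December peaks and an August minimum, about 1.2
#' million residents concentrated in a narrow belt, and daily admissions
#' around 30 with a true exposure-response coefficient of 2e-4 per ug/m^3
#' acting at a 4-day lag.
#'
#' @param seed Integer seed; every stochastic stage derives its own
#'   substream from it.
#' @param year Calendar year of the exposure (interpolation) series.
#' @param n_stations Number of monitoring stations, >= 3.
#' @param domain_bounds `c(lon_min, lat_min, lon_max, lat_max)` degrees.
#' @param resolution Grid cell size in degrees (default 0.01, ~1 km).
#' @param beta_true True exposure-response coefficient, per ug/m^3.
#' @param lag_true True single-day exposure lag in days, >= 0.
#' @param baseline_rate Expected daily admissions at the reference
#'   concentration (`annual_mean_pm10`).
#' @param total_population Persons in the domain.
#' @param seasonal_amplitudes Named vector `c(spring=, winter=)`: peak
#'   multipliers of the two concentration bumps (mid April, mid December).
#' @param summer_dip Depth of the August concentration minimum.
#' @param noise_sd Log-scale sd of per-station idiosyncratic concentration
#'   noise; 0 makes stations exact scaled copies of the regional signal.
#' @param regional_sd Log-scale sd of the day-to-day regional (synoptic)
#'   shock shared by all stations; this is what makes inter-station
#'   correlation high.
#' @param annual_mean_pm10 Target domain-average annual PM10 (ug/m^3); the
#'   TSP baseline is calibrated so the true surface averages to this.
#' @param ridge_amp Relative concentration enhancement on the urban belt
#'   axis (the spatial gradient the kriging has to recover).
#' @param belt_width Gaussian half-width (degrees) of the population belt;
#'   as it tends to zero all mass concentrates in the ridge cells.
#' @param weather_amplitude Scales both the seasonal amplitude and the
#'   noise of the weather series; 0 gives constant series.
#' @param fit_years Calendar years of the admission/confounder series used
#'   for exposure-response fitting.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       year = 2000L,
                       n_stations = 7L,
                       domain_bounds = c(103.50, 35.98, 103.95, 36.13),
                       resolution = 0.01,
                       beta_true = 2e-4,
                       lag_true = 4L,
                       baseline_rate = 30,
                       total_population = 1.2e6,
                       seasonal_amplitudes = c(spring = 0.45, winter = 0.40),
                       summer_dip = 0.30,
                       noise_sd = 0.12,
                       regional_sd = 0.28,
                       annual_mean_pm10 = 330,
                       ridge_amp = 0.20,
                       belt_width = 0.018,
                       weather_amplitude = 1,
                       fit_years = 2001:2005) {
  stop_if_not_scalar_number(seed, "seed")
  stop_if_not_scalar_number(n_stations, "n_stations", lower = 3)
  if (length(domain_bounds) != 4 ||
      domain_bounds[1] >= domain_bounds[3] ||
      domain_bounds[2] >= domain_bounds[4]) {
    stop("domain_bounds must be c(lon_min, lat_min, lon_max, lat_max) with ",
         "positive width and height", call. = FALSE)
  }
  stop_if_not_scalar_number(resolution, "resolution", lower = 1e-6)
  stop_if_not_scalar_number(beta_true, "beta_true")
  if (beta_true < 0) stop("beta_true must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(lag_true, "lag_true", lower = 0)
  stop_if_not_scalar_number(baseline_rate, "baseline_rate", lower = 1e-12)
  stop_if_not_scalar_number(total_population, "total_population",
                            lower = 1e-12)
  stop_if_not_scalar_number(noise_sd, "noise_sd", lower = 0)
  stop_if_not_scalar_number(regional_sd, "regional_sd", lower = 0)
  stop_if_not_scalar_number(belt_width, "belt_width", lower = 1e-12)
  structure(list(
    seed = as.integer(seed), year = as.integer(year),
    n_stations = as.integer(n_stations),
    domain_bounds = as.numeric(domain_bounds), resolution = resolution,
    beta_true = beta_true, lag_true = as.integer(lag_true),
    baseline_rate = baseline_rate, total_population = total_population,
    seasonal_amplitudes = seasonal_amplitudes, summer_dip = summer_dip,
    noise_sd = noise_sd, regional_sd = regional_sd,
    annual_mean_pm10 = annual_mean_pm10, ridge_amp = ridge_amp,
    belt_width = belt_width, weather_amplitude = weather_amplitude,
    fit_years = as.integer(fit_years)
  ), class = "sim_config")
}

# Urban-belt geometry. The belt axis runs WNW -> ESE across the domain with
# a gentle tilt; perpendicular distance to it drives both population
# density and the concentration enhancement.
belt_axis <- function(config) {
  b <- config$domain_bounds
  list(lon_c = (b[1] + b[3]) / 2, lat_c = (b[2] + b[4]) / 2, slope = -0.12)
}

belt_distance <- function(config, lon, lat) {
  ax <- belt_axis(config)
  abs(lat - ax$lat_c - ax$slope * (lon - ax$lon_c)) / sqrt(1 + ax$slope^2)
}

# Longitudinal density profile along the belt: a dominant eastern center
# and a secondary western one, never decaying to zero inside the domain.
belt_profile <- function(config, lon) {
  b <- config$domain_bounds
  u <- (lon - b[1]) / (b[3] - b[1])
  0.35 + 0.65 * exp(-((u - 0.62) / 0.30)^2) +
    0.45 * exp(-((u - 0.15) / 0.10)^2)
}

# True relative concentration field: enhanced on the belt where emissions
# concentrate.
conc_multiplier <- function(config, lon, lat) {
  1 + config$ridge_amp * exp(-(belt_distance(config, lon, lat) / 0.045)^2)
}

#' Analysis grid implied by the configured domain
#'
#' @param config A [sim_config()].
#' @return A [grid_spec()] covering `domain_bounds` at `resolution`.
#' @export
scene_grid <- function(config) {
  b <- config$domain_bounds
  ncols <- max(1L, round((b[3] - b[1]) / config$resolution))
  nrows <- max(1L, round((b[4] - b[2]) / config$resolution))
  grid_spec(b[1], b[2], config$resolution, ncols, nrows)
}

#' Place the monitoring-station network
#'
#' Stations are spread along the urban belt (with a minority deliberately
#' off-belt to sample background air), jittered deterministically from the
#' seed, all strictly inside the domain and pairwise distinct.
#'
#' @param config A [sim_config()].
#' @return Data frame `station_id`, `lon`, `lat`.
#' @export
generate_station_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  b <- config$domain_bounds
  k <- config$n_stations
  with_seed(derive_seed(config$seed, "stations"), {
    for (attempt in 1:20) {
      u <- seq(0.08, 0.92, length.out = k) + stats::runif(k, -0.03, 0.03)
      lon <- b[1] + u * (b[3] - b[1])
      off <- stats::rnorm(k, 0, 0.004)
      bg <- seq(2, k, by = 2)              # every second station off-belt
      if (length(bg)) off[bg] <- 0.065 * (-1)^seq_along(bg)
      ax <- belt_axis(config)
      lat <- ax$lat_c + ax$slope * (lon - ax$lon_c) + off
      m <- config$resolution / 2
      lon <- pmin(pmax(lon, b[1] + m), b[3] - m)
      lat <- pmin(pmax(lat, b[2] + m), b[4] - m)
      d <- dist_deg(cbind(lon, lat))
      if (all(d[upper.tri(d)] > config$resolution / 4)) break
    }
    data.frame(station_id = sprintf("S%02d", seq_len(k)), lon = lon,
               lat = lat, stringsAsFactors = FALSE)
  })
}

# Normalised seasonal multiplier over a vector of dates: unit mean within
# each calendar year, bumps mid-April and mid-December, dip mid-August.
seasonal_factor <- function(config, dates) {
  amps <- config$seasonal_amplitudes
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  nd <- ifelse (((yr %% 4 == 0) & (yr %% 100 != 0)) | (yr %% 400 == 0),
                366L, 365L)
  raw <- function(d, n) {
    1 + amps[["spring"]] * exp(-((d - 105) / 18)^2) +
      amps[["winter"]] * (exp(-((d - 349) / 15)^2) +
                          exp(-((d - 349 + n) / 15)^2)) -
      config$summer_dip * exp(-((d - 227) / 40)^2)
  }
  s <- raw(doy, nd)
  for (y in unique(yr)) {
    i <- yr == y
    n <- nd[i][1]
    s[i] <- s[i] / mean(raw(seq_len(n), n))
  }
  s
}

# TSP baseline calibrated so the true annual-mean PM10 surface averages to
# config$annual_mean_pm10 over the grid.
base_tsp <- function(config) {
  g <- scene_grid(config)
  cc <- cell_centers(g)
  mult <- outer(cc$lat, cc$lon,
                function(la, lo) conc_multiplier(config, lo, la))
  (config$annual_mean_pm10 / 0.55) / mean(mult)
}

#' Generate daily TSP series at the stations
#'
#' Each station records `base * spatial_multiplier * seasonal * regional *
#' idiosyncratic`: the seasonal factor has the configured spring and winter
#' peaks and summer dip, the regional log-normal shock is shared by all
#' stations (high inter-station correlation), and the idiosyncratic
#' log-normal noise is station-specific. Both log-normal terms are
#' mean-corrected so expectations match the deterministic skeleton.
#'
#' @param config A [sim_config()].
#' @param stations Station data frame from [generate_station_network()].
#' @param years Calendar years to simulate (default `config$year`).
#' @return Long data frame `date`, `station_id`, `tsp_ugm3`.
#' @export
generate_tsp_series <- function(config, stations, years = config$year) {
  stopifnot(inherits(config, "sim_config"))
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% years]
  n <- length(dates)
  k <- nrow(stations)
  s <- seasonal_factor(config, dates)
  mult <- conc_multiplier(config, stations$lon, stations$lat)
  b0 <- base_tsp(config)
  with_seed(derive_seed(config$seed, paste0("tsp", min(years))), {
    reg <- exp(stats::rnorm(n, 0, config$regional_sd) -
                 config$regional_sd^2 / 2)
    eps <- matrix(
      exp(stats::rnorm(n * k, 0, config$noise_sd) - config$noise_sd^2 / 2),
      n, k)
    tsp <- (b0 * s * reg) %o% mult * eps
    data.frame(
      date = rep(dates, times = k),
      station_id = rep(stations$station_id, each = n),
      tsp_ugm3 = as.numeric(tsp),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate the belt-shaped population raster
#'
#' An anisotropic Gaussian ridge along the belt axis, with two density
#' centers, truncated to zero in the far periphery and rescaled so cell
#' populations sum exactly to `total_population`.
#'
#' @param config A [sim_config()].
#' @return A population `ah_raster` (persons per cell).
#' @export
generate_population_raster <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- scene_grid(config)
  if (g$ncols * g$nrows < 100) {
    stop("resolution too coarse: need at least 100 grid cells",
         call. = FALSE)
  }
  cc <- cell_centers(g)
  dperp <- outer(cc$lat, cc$lon,
                 function(la, lo) belt_distance(config, lo, la))
  prof <- matrix(belt_profile(config, cc$lon), g$nrows, g$ncols,
                 byrow = TRUE)
  dens_rel <- prof * exp(-(dperp / config$belt_width)^2)
  dens_rel[dens_rel < 0.02 * max(dens_rel)] <- 0
  area <- matrix(cell_area_km2(g), g$nrows, g$ncols)
  pop <- dens_rel * area
  pop <- pop * (config$total_population / sum(pop))
  new_raster(g, pop, units = "persons")
}

#' Generate daily weather confounders
#'
#' Smooth seasonal sinusoids plus noise for temperature (max/mean/min with
#' guaranteed ordering), station pressure and relative humidity; amplitudes
#' and noise scale with `config$weather_amplitude`.
#'
#' @param config A [sim_config()].
#' @param years Calendar years (default `config$fit_years`).
#' @return Data frame `date`, `t_max`, `t_min`, `t_mean`, `pressure_hpa`,
#'   `rh_pct`.
#' @export
generate_confounders <- function(config, years = config$fit_years) {
  stopifnot(inherits(config, "sim_config"))
  a <- config$weather_amplitude
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% years]
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  cyc <- sin(2 * pi * (doy - 105) / 365.25)
  with_seed(derive_seed(config$seed, "weather"), {
    t_mean <- 9 + a * (14 * cyc + stats::rnorm(n, 0, 1.5))
    t_max <- t_mean + 5.5 + a * abs(stats::rnorm(n, 0, 1.8))
    t_min <- t_mean - 6.5 - a * abs(stats::rnorm(n, 0, 1.8))
    pressure <- 845 - a * (6 * cyc + stats::rnorm(n, 0, 2))
    rh <- pmin(pmax(55 + a * (15 * sin(2 * pi * (doy - 166) / 365.25) +
                                stats::rnorm(n, 0, 6)), 5), 100)
    data.frame(date = dates, t_max = t_max, t_min = t_min, t_mean = t_mean,
               pressure_hpa = pressure, rh_pct = rh)
  })
}

# Day-of-week log-rate offsets in the admissions DGP (Monday reference).
dow_effects <- c(Mon = 0, Tue = 0.01, Wed = 0.02, Thu = 0, Fri = 0.03,
                 Sat = -0.08, Sun = -0.12)

dow_index <- function(dates) {
  # 1 = Monday ... 7 = Sunday, locale-independent
  (as.integer(format(dates, "%u")))
}

#' Generate daily hospital admissions from a known Poisson process
#'
#' Counts are Poisson with log-mean `log(baseline_rate) + DOW +
#' beta_true * (PM10 lagged by lag_true - reference) + smooth(time) +
#' smooth(t_max)`. The first `lag_true` days are dropped so every retained
#' day has a defined lagged exposure. The realized log-mean is returned as
#' part of the truth record.
#'
#' @param pm10_series Daily exposure series (ug/m^3), e.g. the station-mean
#'   PM10, aligned with `confounders$date`.
#' @param confounders Data frame from [generate_confounders()].
#' @param config A [sim_config()].
#' @return A list: `data` (date, admissions, weather columns, same-day
#'   `pm10_ugm3`) and `truth` (`beta_true`, `lag_true`, `alpha`,
#'   `pm10_ref`, realized `log_mu`).
#' @export
generate_admissions <- function(pm10_series, confounders, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(pm10_series)
  if (n != nrow(confounders)) {
    stop("pm10_series and confounders must be aligned", call. = FALSE)
  }
  lag <- config$lag_true
  if (n < lag + 1) {
    stop("exposure series shorter than lag_true + 1", call. = FALSE)
  }
  keep <- (lag + 1):n
  pm_lag <- pm10_series[keep - lag]
  dat <- confounders[keep, , drop = FALSE]
  tt <- seq_along(keep)
  u <- (tt - length(tt) / 2) / (length(tt) / 2)
  f_time <- 0.10 * u - 0.06 * u^2
  f_weather <- 0.010 * (dat$t_max - 15) + 0.0002 * (dat$t_max - 15)^2
  alpha <- log(config$baseline_rate)
  log_mu <- alpha + dow_effects[dow_index(dat$date)] +
    config$beta_true * (pm_lag - config$annual_mean_pm10) +
    f_time + f_weather
  y <- with_seed(derive_seed(config$seed, "admissions"),
                 stats::rpois(length(log_mu), exp(log_mu)))
  out <- data.frame(date = dat$date, admissions = y,
                    t_max = dat$t_max, t_min = dat$t_min,
                    t_mean = dat$t_mean, pressure_hpa = dat$pressure_hpa,
                    rh_pct = dat$rh_pct,
                    pm10_ugm3 = pm10_series[keep])
  truth <- list(beta_true = config$beta_true, lag_true = lag,
                alpha = alpha, pm10_ref = config$annual_mean_pm10,
                log_mu = as.numeric(log_mu))
  list(data = out, truth = truth)
}

#' Station-mean daily PM10 from a long TSP table
#'
#' @param tsp Long data frame from [generate_tsp_series()].
#' @param factor TSP-to-PM10 conversion factor.
#' @return Data frame `date`, `pm10_ugm3` (network mean).
#' @export
station_mean_pm10 <- function(tsp, factor = 0.55) {
  pm <- tsp_to_pm10(tsp$tsp_ugm3, factor)
  agg <- tapply(pm, tsp$date, mean)
  data.frame(date = as.Date(names(agg)), pm10_ugm3 = as.numeric(agg))
}

#' Generate a complete synthetic scene
#'
#' Produces every pipeline input plus the truth record that downstream
#' recovery tests compare against: the station network, the exposure-year
#' TSP series, the population raster, the true annual-mean concentration
#' raster, multi-year weather and admissions for model fitting, and the
#' closed-form expected excess cases per threshold scenario.
#'
#' @param config A [sim_config()].
#' @param scenarios Data frame of threshold scenarios (`label`, `c0`);
#'   default [default_scenarios()].
#' @return A list of class `synthetic_scene`.
#' @export
generate_scene <- function(config, scenarios = default_scenarios()) {
  stopifnot(inherits(config, "sim_config"))
  stations <- generate_station_network(config)
  tsp <- generate_tsp_series(config, stations, years = config$year)
  pop <- generate_population_raster(config)
  g <- scene_grid(config)
  cc <- cell_centers(g)
  mult <- outer(cc$lat, cc$lon,
                function(la, lo) conc_multiplier(config, lo, la))
  conc_true <- new_raster(g, base_tsp(config) * 0.55 * mult,
                          units = "ug/m3")
  conf <- generate_confounders(config, years = config$fit_years)
  tsp_fit <- generate_tsp_series(config, stations,
                                 years = config$fit_years)
  pm_fit <- station_mean_pm10(tsp_fit)
  adm <- generate_admissions(pm_fit$pm10_ugm3, conf, config)

  # Closed-form expected annual excess cases per scenario on the true
  # surface, via the identity N = P * E0 * (exp(beta * dC) - 1).
  e0 <- config$baseline_rate / config$total_population
  tab_true <- overlay(conc_true, pop)
  expected <- vapply(seq_len(nrow(scenarios)), function(i) {
    dc <- pmax(tab_true$pm10_ugm3 - scenarios$c0[i], 0)
    365 * sum(tab_true$population * e0 *
                (exp(config$beta_true * dc) - 1))
  }, numeric(1))
  truth <- c(adm$truth,
             list(e0 = e0,
                  expected_excess_cases = stats::setNames(expected,
                                                          scenarios$label),
                  scenario_c0 = stats::setNames(scenarios$c0,
                                                scenarios$label)))
  structure(list(config = config, stations = stations, tsp = tsp,
                 population = pop, conc_true = conc_true,
                 confounders = conf, pm10_fit = pm_fit,
                 admissions = adm$data, truth = truth),
            class = "synthetic_scene")
}

#' Write a synthetic scene to disk in interchange formats
#'
#' Writes `stations.geojson`, `tsp_daily.csv`, `population.asc`,
#' `admissions.csv` and `truth.json` under `dir`.
#'
#' @param scene A `synthetic_scene` from [generate_scene()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    stations = file.path(dir, "stations.geojson"),
    tsp = file.path(dir, "tsp_daily.csv"),
    population = file.path(dir, "population.asc"),
    admissions = file.path(dir, "admissions.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_stations_geojson(scene$stations, paths["stations"])
  write_csv_plain(scene$tsp, paths["tsp"])
  write_asc(scene$population, paths["population"])
  write_csv_plain(scene$admissions, paths["admissions"])
  tr <- scene$truth
  tr$log_mu <- NULL  # keep the JSON record compact
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
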