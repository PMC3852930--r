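# Shared fixtures, built once per test run. The default scene (seed 1) and
# its kriged surface are reused across files; tests that need different
# parameters build their own configs.

default_config <- sim_config(seed = 1L)

default_scene <- generate_scene(default_config)

# Kriged exposure chain on the default scene: station annual-mean PM10,
# fitted variogram, surface, overlay table.
default_chain <- local({
  st <- default_scene$stations
  tsp <- default_scene$tsp
  pm <- tapply(tsp_to_pm10(tsp$tsp_ugm3), tsp$station_id, mean)
  pm <- as.numeric(pm[st$station_id])
  vgm <- fit_variogram(st[, c("lon", "lat")], pm)
  surface <- krige_surface(st, pm, default_scene$population$grid, vgm)
  tab <- overlay(surface, default_scene$population)
  list(stations = st, station_pm10 = pm, vgm = vgm, surface = surface,
       table = tab)
})

# One fitted synthetic dataset per seed: the admission series and the
# design/fit at the true lag with the default smooth set.
make_fit_dataset <- function(seed, beta_true = 2e-4, ...) {
  cfg <- sim_config(seed = seed, beta_true = beta_true, ...)
  st <- generate_station_network(cfg)
  conf <- generate_confounders(cfg)
  tsp <- generate_tsp_series(cfg, st, years = cfg$fit_years)
  pm <- station_mean_pm10(tsp)
  generate_admissions(pm$pm10_ugm3, conf, cfg)
}

default_smooths <- list(time = 4, t_max = 3, pressure_hpa = 3)
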