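# Ordinary kriging: best linear unbiased prediction with weights constrained
# to sum to 1, driven by a fitted variogram. One (n+1)x(n+1) system is
# factorised once and solved against all prediction points at once.

#' Ordinary-kriging prediction at arbitrary points
#'
#' @param coords Two-column (lon, lat) matrix of station locations, degrees.
#' @param values Station values.
#' @param vgm A [variogram_model()].
#' @param new_coords Two-column (lon, lat) matrix of prediction points.
#' @return A list with `values` (predictions) and `weights` (an
#'   `n_stations x n_points` matrix of kriging weights; each column sums
#'   to 1).
#' @export
krige_points <- function(coords, values, vgm, new_coords) {
  stopifnot(inherits(vgm, "variogram_model"))
  coords <- as.matrix(as.data.frame(coords)[, 1:2])
  new_coords <- as.matrix(as.data.frame(new_coords)[, 1:2])
  n <- nrow(coords)
  if (length(values) != n) stop("values must match coords", call. = FALSE)
  d <- dist_deg(coords)
  if (n > 1 && any(d[upper.tri(d)] < 1e-12)) {
    stop("singular kriging system: duplicate station locations", call. = FALSE)
  }
  A <- matrix(0, n + 1, n + 1)
  A[1:n, 1:n] <- vgm_gamma(vgm, d)
  A[n + 1, 1:n] <- 1
  A[1:n, n + 1] <- 1
  d0 <- dist_deg(coords, new_coords)          # n x m
  B <- rbind(vgm_gamma(vgm, d0), 1)           # (n+1) x m
  sol <- tryCatch(solve(A, B), error = function(e) {
    stop("singular kriging system: ", conditionMessage(e), call. = FALSE)
  })
  w <- sol[1:n, , drop = FALSE]
  list(values = as.numeric(crossprod(w, values)), weights = w)
}

#' Krige station values onto an analysis grid
#'
#' Evaluates ordinary kriging at every cell center of `grid`. With a zero
#' nugget the surface passes exactly through the station values.
#'
#' @param stations Data frame with `lon`, `lat` (and optionally
#'   `station_id`).
#' @param values One value per station (e.g. annual-mean PM10, ug/m^3).
#' @param grid Target [grid_spec()].
#' @param vgm A [variogram_model()].
#' @param units Unit label for the output raster.
#' @return An `ah_raster` of predictions.
#' @export
krige_surface <- function(stations, values, grid, vgm, units = "ug/m3") {
  stopifnot(inherits(grid, "grid_spec"))
  cc <- cell_centers(grid)
  pts <- cbind(lon = rep(cc$lon, each = grid$nrows),
               lat = rep(cc$lat, times = grid$ncols))
  kr <- krige_points(stations[, c("lon", "lat")], values, vgm, pts)
  m <- matrix(kr$values, nrow = grid$nrows, ncol = grid$ncols)
  new_raster(grid, m, units = units)
}
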