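# Exposure-surface operations: unit conversion, population disaggregation,
# raster overlay, population-weighted exposure and its distribution.

#' Convert total suspended particulates to PM10
#'
#' PM10 is estimated from TSP with a fixed multiplicative conversion factor
#' (default 0.55), the standard approach when a network measures TSP only.
#'
#' @param tsp TSP concentrations, ug/m^3, >= 0.
#' @param factor Conversion factor (default 0.55).
#' @return PM10 concentrations, ug/m^3.
#' @export
tsp_to_pm10 <- function(tsp, factor = 0.55) {
  if (any(!is.finite(tsp)) || any(tsp < 0)) {
    stop("TSP concentrations must be finite and non-negative", call. = FALSE)
  }
  tsp * factor
}

# 1-D overlap weights between target and source cell-edge intervals:
# entry [t, s] is the fraction of source interval s covered by target
# interval t.
overlap_weights <- function(t_edges, s_edges) {
  nt <- length(t_edges) - 1L
  ns <- length(s_edges) - 1L
  w <- matrix(0, nt, ns)
  slen <- diff(s_edges)
  for (t in seq_len(nt)) {
    lo <- pmax(t_edges[t], s_edges[-length(s_edges)])
    hi <- pmin(t_edges[t + 1], s_edges[-1])
    w[t, ] <- pmax(hi - lo, 0) / slen
  }
  w
}

#' Mass-preserving disaggregation of a population raster
#'
#' Areal-weighted interpolation: each source cell's population is split
#' among target cells in proportion to overlap area, so total population is
#' conserved whenever the target grid covers the source extent.
#'
#' @param source A population `ah_raster` (persons per cell).
#' @param target A [grid_spec()] for the output resolution.
#' @return A population `ah_raster` on `target`.
#' @export
interpolate_population <- function(source, target) {
  stopifnot(inherits(source, "ah_raster"), inherits(target, "grid_spec"))
  sg <- source$grid
  s_lon <- sg$lon_min + 0:sg$ncols * sg$cellsize
  s_lat_desc <- sg$lat_min + sg$nrows:0 * sg$cellsize  # north -> south edges
  t_lon <- target$lon_min + 0:target$ncols * target$cellsize
  t_lat_desc <- target$lat_min + target$nrows:0 * target$cellsize
  if (t_lon[1] >= s_lon[length(s_lon)] || t_lon[length(t_lon)] <= s_lon[1] ||
      target$lat_min >= s_lat_desc[1] ||
      t_lat_desc[1] <= sg$lat_min) {
    stop("source and target extents are disjoint", call. = FALSE)
  }
  wx <- overlap_weights(t_lon, s_lon)
  # latitude intervals run north->south; convert edges to increasing order
  # per row pairing by reversing, then reverse back
  wy <- overlap_weights(rev(t_lat_desc), rev(s_lat_desc))
  wy <- wy[rev(seq_len(nrow(wy))), rev(seq_len(ncol(wy))), drop = FALSE]
  v <- source$values
  v[is.na(v)] <- 0
  out <- wy %*% v %*% t(wx)
  total_in <- sum(v)
  total_out <- sum(out)
  if (total_in > 0 && abs(total_out - total_in) / total_in > 0.001) {
    warning(sprintf(
      "population not conserved: target grid covers %.2f%% of source mass",
      100 * total_out / total_in))
  }
  new_raster(target, out, units = source$units)
}

#' Overlay concentration and population rasters into an exposure table
#'
#' One row per grid cell that has population > 0 and a valid (non-NODATA)
#' concentration. Cells with population but missing concentration are
#' dropped; their count is attached as attribute `"n_dropped_nodata"`.
#'
#' @param conc Concentration `ah_raster` (ug/m^3).
#' @param pop Population `ah_raster` (persons per cell), co-registered with
#'   `conc`.
#' @return Data frame with `cell_id`, `row`, `col` (0-based, row 0 north),
#'   `lon`, `lat` (cell centers), `population`, `pm10_ugm3`.
#' @export
overlay <- function(conc, pop) {
  stopifnot(inherits(conc, "ah_raster"), inherits(pop, "ah_raster"))
  if (!same_grid(conc$grid, pop$grid)) {
    stop("concentration and population rasters are not co-registered",
         call. = FALSE)
  }
  g <- conc$grid
  cc <- cell_centers(g)
  idx <- which(!is.na(pop$values) & pop$values > 0, arr.ind = TRUE)
  r <- idx[, 1]; cl <- idx[, 2]
  cv <- conc$values[idx]
  keep <- !is.na(cv)
  dropped <- sum(!keep)
  r <- r[keep]; cl <- cl[keep]; cv <- cv[keep]
  out <- data.frame(
    cell_id = (r - 1L) * g$ncols + (cl - 1L),
    row = r - 1L,
    col = cl - 1L,
    lon = cc$lon[cl],
    lat = cc$lat[r],
    population = pop$values[cbind(r, cl)],
    pm10_ugm3 = cv
  )
  out <- out[order(out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_nodata") <- dropped
  out
}

#' Population-weighted exposure level (PWEL)
#'
#' `sum(P_i * C_i) / sum(P_i)` over the exposure table's grid cells.
#'
#' @param table An exposure table from [overlay()].
#' @return PWEL in ug/m^3.
#' @export
population_weighted_exposure <- function(table) {
  stopifnot(all(c("population", "pm10_ugm3") %in% names(table)))
  tp <- sum(table$population)
  if (!is.finite(tp) || tp <= 0) {
    stop("total population must be positive", call. = FALSE)
  }
  sum(table$population * table$pm10_ugm3) / tp
}

#' Population distribution across concentration bins
#'
#' Bins are left-closed, right-open, with the last bin closed, so a value on
#' an interior edge counts in the bin that starts at that edge.
#'
#' @param table An exposure table from [overlay()].
#' @param bin_edges Strictly increasing edges covering the full range of
#'   concentrations in the table.
#' @return Named numeric vector of persons per bin; sums to the total
#'   population of the table.
#' @export
exposure_distribution <- function(table, bin_edges) {
  if (any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  c_ <- table$pm10_ugm3
  if (min(c_) < bin_edges[1] || max(c_) > bin_edges[length(bin_edges)]) {
    bad <- c_[c_ < bin_edges[1] | c_ > bin_edges[length(bin_edges)]][1]
    stop(sprintf("bin edges do not cover concentration %.6g", bad),
         call. = FALSE)
  }
  k <- findInterval(c_, bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1L
  counts <- vapply(seq_len(nb),
                   function(j) sum(table$population[k == j]), numeric(1))
  names(counts) <- sprintf("[%g,%g%s", bin_edges[-length(bin_edges)],
                           bin_edges[-1],
                           c(rep(")", nb - 1L), "]"))
  counts
}

#' Pearson correlation between two station series
#'
#' Computed over paired non-missing days; used to judge how well one
#' station represents the network.
#'
#' @param series_a,series_b Numeric vectors of equal length.
#' @return Pearson product-moment correlation in [-1, 1].
#' @export
station_correlation <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) {
    stop("series must have equal length", call. = FALSE)
  }
  ok <- is.finite(series_a) & is.finite(series_b)
  if (sum(ok) < 3) stop("need at least 3 paired non-missing days",
                        call. = FALSE)
  a <- series_a[ok]; b <- series_b[ok]
  if (stats::var(a) < 1e-300 || stats::var(b) < 1e-300) {
    stop("zero variance in a series; correlation undefined", call. = FALSE)
  }
  stats::cor(a, b)
}
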