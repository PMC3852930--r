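#' Define a regular geographic analysis grid
#'
#' A grid of square cells in plain geographic degrees, addressed by 0-based
#' (row, col) with row 0 at the north edge (the ESRI ASCII grid convention).
#' `lon_min`/`lat_min` give the lower-left cell-edge origin; cell centers sit
#' at `origin + (index + 0.5) * cellsize`.
#'
#' @param lon_min,lat_min Lower-left corner (cell edge), degrees.
#' @param cellsize Cell size in degrees (default 0.01, roughly 1 km).
#' @param ncols,nrows Number of columns / rows.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(lon_min, lat_min, cellsize = 0.01, ncols, nrows) {
  stop_if_not_scalar_number(cellsize, "cellsize", lower = 1e-12)
  stop_if_not_scalar_number(ncols, "ncols", lower = 1)
  stop_if_not_scalar_number(nrows, "nrows", lower = 1)
  structure(
    list(lon_min = lon_min, lat_min = lat_min, cellsize = cellsize,
         ncols = as.integer(ncols), nrows = as.integer(nrows)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d cols x %d rows at %g deg, origin (%.4f, %.4f)\n",
              x$ncols, x$nrows, x$cellsize, x$lon_min, x$lat_min))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  inherits(a, "grid_spec") && inherits(b, "grid_spec") &&
    a$ncols == b$ncols && a$nrows == b$nrows &&
    abs(a$lon_min - b$lon_min) < tol && abs(a$lat_min - b$lat_min) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A list with `lon` (length `ncols`, west to east) and `lat`
#'   (length `nrows`, north to south, matching matrix row order).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  lon <- grid$lon_min + (seq_len(grid$ncols) - 0.5) * grid$cellsize
  lat <- grid$lat_min + (grid$nrows - seq_len(grid$nrows) + 0.5) * grid$cellsize
  list(lon = lon, lat = lat)
}

#' Approximate cell area in square kilometres
#'
#' Uses the spherical-degree lengths at each row's center latitude, so area
#' varies (slightly) with latitude across the grid.
#'
#' @param grid A [grid_spec()].
#' @return A numeric vector of length `nrows` (north to south), km^2.
#' @export
cell_area_km2 <- function(grid) {
  lat <- cell_centers(grid)$lat
  km_per_deg_lat <- 110.574
  km_per_deg_lon <- 111.320 * cos(lat * pi / 180)
  (grid$cellsize * km_per_deg_lon) * (grid$cellsize * km_per_deg_lat)
}

#' Construct a raster layer on a grid
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix `nrows x ncols` (row 1 = north edge), or a
#'   single number recycled. `NA` marks NODATA.
#' @param units Free-text unit label carried along for reporting.
#' @return An object of class `ah_raster`.
#' @export
new_raster <- function(grid, values, units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L) values <- matrix(values, grid$nrows, grid$ncols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$nrows, grid$ncols))) {
    stop("values must be an nrows x ncols matrix matching the grid",
         call. = FALSE)
  }
  structure(list(grid = grid, values = values, units = units),
            class = "ah_raster")
}

#' @export
print.ah_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("ah_raster [%s]: %d x %d cells, %d valid, range %.4g..%.4g\n",
              x$units, x$grid$nrows, x$grid$ncols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` with the standard six-line header; NODATA written as
#' -9999; rows north to south.
#'
#' @param raster An [new_raster()] object.
#' @param path Output file path.
#' @param digits Significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path, digits = 10) {
  stopifnot(inherits(raster, "ah_raster"))
  g <- raster$grid
  hdr <- c(
    sprintf("ncols %d", g$ncols),
    sprintf("nrows %d", g$nrows),
    sprintf("xllcorner %.10g", g$lon_min),
    sprintf("yllcorner %.10g", g$lat_min),
    sprintf("cellsize %.10g", g$cellsize),
    "NODATA_value -9999"
  )
  v <- raster$values
  v[is.na(v)] <- -9999
  body <- apply(v, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path of a `.asc` grid.
#' @param units Unit label to attach.
#' @return An `ah_raster`; NODATA cells become `NA`.
#' @export
read_asc <- function(path, units = "") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                 hdr$ncols, hdr$nrows)
  new_raster(g, m, units = units)
}
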