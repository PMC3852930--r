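# Readers/writers for the plain-text interchange formats the pipeline uses:
# GeoJSON point files for station locations, CSV for daily series, JSON for
# the simulation truth record.

#' Write station locations as GeoJSON points
#'
#' @param stations Data frame with columns `station_id`, `lon`, `lat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stations_geojson <- function(stations, path) {
  stopifnot(all(c("station_id", "lon", "lat") %in% names(stations)))
  feats <- lapply(seq_len(nrow(stations)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(stations$lon[i], stations$lat[i])),
      properties = list(station_id = stations$station_id[i])
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read station locations from GeoJSON points
#'
#' @param path GeoJSON file of Point features with a `station_id` property.
#' @return Data frame with `station_id`, `lon`, `lat`.
#' @export
read_stations_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  rows <- lapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      stop("non-Point feature in ", path, call. = FALSE)
    }
    data.frame(station_id = as.character(f$properties$station_id),
               lon = as.numeric(f$geometry$coordinates[[1]]),
               lat = as.numeric(f$geometry$coordinates[[2]]))
  })
  do.call(rbind, rows)
}

#' Read a daily station pollutant series
#'
#' Expects columns `date` (ISO-8601), `station_id` and a concentration
#' column; concentrations may be recorded in ug/m^3 (the canonical internal
#' unit) or mg/m^3, declared via `unit`.
#'
#' @param path CSV path.
#' @param unit `"ug"` or `"mg"`; mg values are converted to ug on read.
#' @param value_col Name of the concentration column.
#' @return Data frame `date` (Date), `station_id`, `tsp_ugm3`.
#' @export
read_tsp_csv <- function(path, unit = c("ug", "mg"), value_col = NULL) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(value_col)) {
    cand <- setdiff(names(df), c("date", "station_id"))
    value_col <- cand[1]
  }
  out <- data.frame(date = as.Date(df$date),
                    station_id = as.character(df$station_id),
                    tsp_ugm3 = as.numeric(df[[value_col]]))
  if (unit == "mg") out$tsp_ugm3 <- out$tsp_ugm3 * 1000
  if (any(!is.finite(out$tsp_ugm3)) || any(out$tsp_ugm3 < 0)) {
    stop("non-finite or negative concentrations in ", path, call. = FALSE)
  }
  out
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
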