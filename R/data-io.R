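# Reading and writing the canonical per-city daily table, importing
# long-format station weather archives, and matching air-quality sites to
# their nearest weather stations on a spherical Earth.

canonical_columns <- c("date", "no2", "wind_speed", "wind_direction",
                       "temperature", "relative_humidity")

#' Write a city daily series to the canonical delimited format
#'
#' One comma-delimited file per city: ISO-8601 `date` plus the five value
#' columns, empty cells for missing values.
#'
#' @param series City daily series tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_daily_city_table <- function(series, path) {
  readr::write_csv(series[, canonical_columns], path, na = "")
  invisible(path)
}

#' Read a city daily series from the canonical delimited format
#'
#' Parses ISO-8601 dates, sorts rows by date, and rejects physically
#' impossible values to missing: negative concentrations, relative humidity
#' outside \[0, 100\], negative wind speed and wind direction outside
#' \[0, 360). The count of rejected cells is reported as a warning so data
#' accounting stays auditable.
#'
#' @param path File in the layout written by [write_daily_city_table()].
#' @param city_id City label; defaults to the file name without extension.
#' @return City daily series tibble sorted by date.
#' @export
read_daily_city_table <- function(path,
                                  city_id = sub("\\.[^.]*$", "",
                                                basename(path))) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"))
  missing_cols <- setdiff(canonical_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(date)) {
    stop("unparseable date at row(s) ",
         paste(utils::head(which(is.na(date)), 5), collapse = ", "),
         call. = FALSE)
  }
  num <- lapply(raw[setdiff(canonical_columns, "date")],
                function(x) suppressWarnings(as.numeric(x)))
  out <- tibble::tibble(city_id = city_id, date = date, no2 = num$no2,
                        wind_speed = num$wind_speed,
                        wind_direction = num$wind_direction,
                        temperature = num$temperature,
                        relative_humidity = num$relative_humidity)
  reject <- function(x, bad) {
    n_bad <- sum(bad, na.rm = TRUE)
    x[which(bad)] <- NA_real_
    list(x = x, n = n_bad)
  }
  r1 <- reject(out$no2, out$no2 < 0)
  r2 <- reject(out$relative_humidity,
               out$relative_humidity < 0 | out$relative_humidity > 100)
  r3 <- reject(out$wind_speed, out$wind_speed < 0)
  r4 <- reject(out$wind_direction,
               out$wind_direction < 0 | out$wind_direction >= 360)
  out$no2 <- r1$x
  out$relative_humidity <- r2$x
  out$wind_speed <- r3$x
  out$wind_direction <- r4$x
  n_rejected <- r1$n + r2$n + r3$n + r4$n
  if (n_rejected > 0) {
    warning(n_rejected, " out-of-range value(s) set to missing in ", path,
            call. = FALSE)
  }
  if (anyDuplicated(out$date)) {
    stop("duplicate dates in ", path, call. = FALSE)
  }
  out[order(out$date), ]
}

#' Pivot a long station-weather table to daily wide records
#'
#' Long archives (station, date, element code, value) such as GHCN-Daily are
#' converted to one row per date with the four canonical meteorological
#' variables in canonical units. `unit_map` declares, per source element
#' code, the target variable and the multiplicative scale from stored to
#' canonical units (e.g. tenths of a degree Celsius -> 0.1).
#'
#' @param table Tibble with columns `station_id`, `date`, `element`, `value`.
#' @param station_id Station to extract.
#' @param unit_map Named list: element code -> `list(var = , scale = )` where
#'   `var` is one of `wind_speed`, `wind_direction`, `temperature`,
#'   `relative_humidity`. Unknown element codes are skipped with a warning.
#' @return Tibble with `date` plus the four canonical variables (missing
#'   where the element was not reported).
#' @export
pivot_weather <- function(table, station_id, unit_map) {
  rows <- table[table$station_id == station_id, , drop = FALSE]
  if (anyDuplicated(rows[c("station_id", "date", "element")])) {
    stop("duplicate (station, date, element) record for station ", station_id,
         call. = FALSE)
  }
  unknown <- setdiff(unique(rows$element), names(unit_map))
  if (length(unknown) > 0) {
    warning("skipping unmapped element code(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    rows <- rows[rows$element %in% names(unit_map), , drop = FALSE]
  }
  rows$var <- unname(purrr::map_chr(unit_map[rows$element], "var"))
  rows$value <- rows$value *
    unname(purrr::map_dbl(unit_map[rows$element], "scale"))
  wide <- tidyr::pivot_wider(rows[c("date", "var", "value")],
                             names_from = "var", values_from = "value")
  for (v in c("wind_speed", "wind_direction", "temperature",
              "relative_humidity")) {
    if (!v %in% names(wide)) wide[[v]] <- NA_real_
  }
  wide <- wide[order(wide$date),
               c("date", "wind_speed", "wind_direction", "temperature",
                 "relative_humidity")]
  wide
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Match a monitoring site to its nearest weather station
#'
#' @param site One-row tibble (or list) with `station_id`, `latitude`,
#'   `longitude`.
#' @param candidates Tibble of candidate stations with the same columns.
#'   Ties in distance are broken by lexicographic `station_id`.
#' @return The winning candidate row with an extra `distance_km` column.
#' @export
match_nearest_station <- function(site, candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("empty candidate station list", call. = FALSE)
  }
  stopifnot(all(abs(candidates$latitude) <= 90),
            all(abs(candidates$longitude) <= 180))
  d <- great_circle_km(site$latitude, site$longitude,
                       candidates$latitude, candidates$longitude)
  best <- which(d == min(d))
  if (length(best) > 1) {
    best <- best[order(candidates$station_id[best])][1]
  }
  out <- candidates[best, , drop = FALSE]
  out$distance_km <- d[best]
  out
}
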