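# Calendar predictors: the winter-season label, day of year, weekday, and the
# holiday-relative day count around the Chinese Lunar New Year, assembled with
# the meteorology into the model-ready feature table.

#' Holiday calendar for the Chinese Lunar New Year
#'
#' A lookup from year to the first day of the Lunar New Year holiday in that
#' year. The anchor used throughout is 27 January for 2017; shipped defaults
#' for the other study winters follow the official holiday start and can be
#' overridden (e.g. if a user prefers New Year's Day itself, one day later
#' for 2017).
#'
#' @param entries Named character or Date vector, names are years and values
#'   the first holiday day. Dates must fall in January or February of the
#'   named year.
#' @return Named `Date` vector of class `holiday_calendar`.
#' @export
holiday_calendar <- function(entries = c(`2017` = "2017-01-27",
                                         `2018` = "2018-02-16",
                                         `2019` = "2019-02-05",
                                         `2020` = "2020-01-25")) {
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("`entries` must be named by year", call. = FALSE)
  }
  dates <- as.Date(unname(unlist(entries)))
  if (anyNA(dates)) stop("unparseable holiday date in `entries`", call. = FALSE)
  yrs <- as.integer(names(entries))
  if (any(as.integer(format(dates, "%Y")) != yrs)) {
    stop("each holiday date must fall in its named year", call. = FALSE)
  }
  if (any(!format(dates, "%m") %in% c("01", "02"))) {
    stop("holiday dates must fall in January or February", call. = FALSE)
  }
  structure(stats::setNames(dates, names(entries)),
            class = c("holiday_calendar", "Date"))
}

#' Winter season label of a date
#'
#' Each analysis winter runs 1 December to 30 April and is labelled by the
#' calendar year containing its April end, so December dates belong to the
#' following year's season (and reference the upcoming holiday).
#'
#' @param date `Date` vector.
#' @return Integer vector of season labels.
#' @export
season_of <- function(date) {
  date <- as.Date(date)
  as.integer(format(date, "%Y")) + as.integer(format(date, "%m") == "12")
}

#' Days relative to the first day of the Lunar New Year holiday
#'
#' The signed number of calendar days between `date` and the first holiday
#' day of the winter season containing `date`: negative before, zero on the
#' holiday's first day, positive after. For example, with the holiday
#' starting 27 January 2017, the 26th-28th map to -1, 0, 1.
#'
#' @param date `Date` vector (or coercible).
#' @param cal A [holiday_calendar()].
#' @return Integer vector of signed day counts.
#' @export
day_lunar <- function(date, cal = holiday_calendar()) {
  date <- as.Date(date)
  season <- season_of(date)
  missing_seasons <- setdiff(unique(season), as.integer(names(cal)))
  if (length(missing_seasons) > 0) {
    stop("holiday calendar has no entry for season(s) ",
         paste(missing_seasons, collapse = ", "), call. = FALSE)
  }
  anchor <- as.Date(unclass(cal), origin = "1970-01-01")
  names(anchor) <- names(cal)
  as.integer(date - anchor[as.character(season)])
}

#' Weekday number, Monday = 1 through Sunday = 7
#' @param date `Date` vector.
#' @return Integer vector in 1..7.
#' @export
weekday_number <- function(date) {
  ((as.POSIXlt(as.Date(date))$wday + 6L) %% 7L) + 1L
}

#' Build the model-ready feature table for one city
#'
#' One row per day of the input series with the four time predictors (season
#' label `year`, `day_julian`, `weekday`, `day_lunar`), the four
#' meteorological predictors, and the NO2 response. Rows with any missing
#' predictor or response are retained but flagged `incomplete`; model fitting
#' and prediction skip them.
#'
#' @param series A city daily series as returned by [generate_city()] or
#'   [read_daily_city_table()].
#' @param cal A [holiday_calendar()] covering every season in the series.
#' @return Tibble with columns `city_id`, `date`, `year`, `day_julian`,
#'   `weekday`, `day_lunar`, `wind_speed`, `wind_direction`, `temperature`,
#'   `relative_humidity`, `no2`, `incomplete`.
#' @export
build_features <- function(series, cal = holiday_calendar()) {
  if (nrow(series) == 0) stop("empty series", call. = FALSE)
  lt <- as.POSIXlt(series$date)
  out <- tibble::tibble(
    city_id = series$city_id,
    date = series$date,
    year = season_of(series$date),
    day_julian = lt$yday + 1L,
    weekday = weekday_number(series$date),
    day_lunar = day_lunar(series$date, cal),
    wind_speed = series$wind_speed,
    wind_direction = series$wind_direction,
    temperature = series$temperature,
    relative_humidity = series$relative_humidity,
    no2 = series$no2
  )
  value_cols <- c("wind_speed", "wind_direction", "temperature",
                  "relative_humidity", "no2")
  out$incomplete <- Reduce(`|`, lapply(out[value_cols], is.na))
  out
}
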