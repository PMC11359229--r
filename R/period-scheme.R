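# The analysis windows: pre-lockdown / lockdown / post-lockdown in the
# 2019-20 winter, and the three reference winters used to train the
# business-as-usual models.

#' Define the analysis period scheme
#'
#' Defaults follow the national timeline: the pre-lockdown window runs from
#' 1 December 2019 to 22 January 2020, the lockdown window from 23 January
#' (the Wuhan lockdown start) to 18 March 2020, and the post-lockdown window
#' from 19 March to 30 April 2020. The three preceding Dec 1 - Apr 30 winters
#' (labelled 2017, 2018, 2019 by their April end) are the reference winters.
#' Per-city deviations (e.g. a longer lockdown) can be expressed by passing
#' different boundary dates.
#'
#' @param pre_start,pre_end Pre-lockdown window boundaries (inclusive).
#' @param lockdown_start,lockdown_end Lockdown window boundaries (inclusive).
#' @param post_start,post_end Post-lockdown window boundaries (inclusive).
#' @param reference_years Integer season labels of the reference winters.
#' @return A list of class `period_scheme` with `Date` interval fields.
#' @export
period_scheme <- function(pre_start = "2019-12-01", pre_end = "2020-01-22",
                          lockdown_start = "2020-01-23",
                          lockdown_end = "2020-03-18",
                          post_start = "2020-03-19", post_end = "2020-04-30",
                          reference_years = c(2017L, 2018L, 2019L)) {
  iv <- function(a, b) c(as.Date(a), as.Date(b))
  scheme <- structure(
    list(
      pre_lockdown = iv(pre_start, pre_end),
      lockdown = iv(lockdown_start, lockdown_end),
      post_lockdown = iv(post_start, post_end),
      reference_years = as.integer(reference_years)
    ),
    class = "period_scheme"
  )
  for (p in c("pre_lockdown", "lockdown", "post_lockdown")) {
    if (scheme[[p]][1] > scheme[[p]][2]) {
      stop("period `", p, "` has start after end", call. = FALSE)
    }
  }
  if (scheme$pre_lockdown[2] + 1 != scheme$lockdown[1] ||
      scheme$lockdown[2] + 1 != scheme$post_lockdown[1]) {
    stop("pre-lockdown, lockdown and post-lockdown windows must be ",
         "contiguous and disjoint", call. = FALSE)
  }
  scheme
}

#' Daily dates of one analysis period
#'
#' @param scheme A [period_scheme()].
#' @param period One of `"pre_lockdown"`, `"lockdown"`, `"post_lockdown"`.
#' @return `Date` vector covering the period, one element per day.
#' @export
period_dates <- function(scheme,
                         period = c("pre_lockdown", "lockdown",
                                    "post_lockdown")) {
  period <- match.arg(period)
  seq(scheme[[period]][1], scheme[[period]][2], by = "day")
}

#' @export
print.period_scheme <- function(x, ...) {
  cat("Analysis period scheme\n")
  for (p in c("pre_lockdown", "lockdown", "post_lockdown")) {
    cat(sprintf("  %-13s %s .. %s (%d days)\n", p, x[[p]][1], x[[p]][2],
                as.integer(x[[p]][2] - x[[p]][1]) + 1L))
  }
  cat("  reference winters:", paste(x$reference_years, collapse = ", "), "\n")
  invisible(x)
}

# All dates of one Dec 1 - Apr 30 winter labelled by its April year.
winter_dates <- function(season) {
  seq(as.Date(sprintf("%d-12-01", season - 1L)),
      as.Date(sprintf("%d-04-30", season)), by = "day")
}

# Map dates of a 2020-winter period onto the same month-day window of a
# reference winter. Feb 29 is dropped when the target winter has none.
shift_period_to_season <- function(dates, season) {
  from_season <- season_of(dates[1])
  out <- as.Date(paste0(as.integer(format(dates, "%Y")) - (from_season - season),
                        format(dates, "-%m-%d")))
  out[!is.na(out)]
}
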