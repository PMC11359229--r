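# Lockdown attribution: period means, the difference-to-difference
# estimator, the machine-learning (observed minus counterfactual) estimator,
# and the cohort-level comparison of the two.

count_expected_days <- function(dates) length(dates)

mean_over_dates <- function(series, dates, min_coverage, label) {
  rows <- series[series$date %in% dates, , drop = FALSE]
  ok <- sum(!is.na(rows$no2))
  coverage <- ok / length(dates)
  if (coverage < min_coverage) {
    stop(sprintf("period `%s` has coverage %.0f%% (< %.0f%% required)",
                 label, 100 * coverage, 100 * min_coverage), call. = FALSE)
  }
  mean(rows$no2, na.rm = TRUE)
}

#' Period mean concentrations for the 2020 winter and its reference winters
#'
#' Computes the six means entering the difference-to-difference estimator:
#' the observed 2020 mean for each of the pre-lockdown, lockdown and
#' post-lockdown windows, and the corresponding historical means over the
#' reference winters. Each 2020 window is mapped onto the identical
#' month-day window of each reference winter (29 February is dropped where
#' the reference winter has none); the historical mean averages days within
#' each winter first, then the winters with equal weight, so unequal
#' missingness cannot tilt the year weighting.
#'
#' @param series City daily series covering all four winters.
#' @param scheme A [period_scheme()].
#' @param min_coverage Minimum fraction of non-missing days required per
#'   period per winter (default 0.7).
#' @return Named list: `c2020_blp`, `c2020_dlp`, `c2020_alp`, `chist_blp`,
#'   `chist_dlp`, `chist_alp`.
#' @export
period_means <- function(series, scheme = period_scheme(),
                         min_coverage = 0.7) {
  periods <- list(blp = period_dates(scheme, "pre_lockdown"),
                  dlp = period_dates(scheme, "lockdown"),
                  alp = period_dates(scheme, "post_lockdown"))
  out <- list()
  for (p in names(periods)) {
    out[[paste0("c2020_", p)]] <-
      mean_over_dates(series, periods[[p]], min_coverage,
                      paste0("2020 ", toupper(p)))
    per_year <- vapply(scheme$reference_years, function(y) {
      mean_over_dates(series, shift_period_to_season(periods[[p]], y),
                      min_coverage, sprintf("%d %s", y, toupper(p)))
    }, numeric(1))
    out[[paste0("chist_", p)]] <- mean(per_year)
  }
  out
}

#' Difference-to-difference lockdown estimator
#'
#' From the six period means, forms the 2020-minus-historical difference for
#' each window and adjusts the lockdown-window difference by subtracting the
#' pre-lockdown difference, removing the shared year-specific offset that a
#' plain historical comparison would misattribute to the lockdown.
#'
#' @param means Output of [period_means()].
#' @return Named list: `cd_blp`, `cd_dlp`, `cd_alp`, `cadj_d_dlp` (all
#'   ug/m3; negative = reduction).
#' @export
diff_to_diff <- function(means) {
  cd_blp <- means$c2020_blp - means$chist_blp
  cd_dlp <- means$c2020_dlp - means$chist_dlp
  cd_alp <- means$c2020_alp - means$chist_alp
  list(cd_blp = cd_blp, cd_dlp = cd_dlp, cd_alp = cd_alp,
       cadj_d_dlp = cd_dlp - cd_blp)
}

#' Machine-learning lockdown estimator
#'
#' The observed lockdown-period mean minus the counterfactual
#' (business-as-usual) mean, with the percent change expressed relative to
#' the counterfactual — i.e. relative to what would have occurred without
#' the lockdown.
#'
#' @param observed Tibble with `date`, `no2` for lockdown-period days.
#' @param counterfactual Tibble with `date`, `no2_pred` from
#'   [predict_counterfactual()].
#' @param n_expected Calendar length of the lockdown window in days
#'   (default 56).
#' @param min_coverage Minimum fraction of paired complete days required.
#' @return Named list: `delta_ml` (ug/m3, negative = reduction),
#'   `percent_change` (%), `n_days_used`.
#' @export
ml_reduction <- function(observed, counterfactual, n_expected = 56,
                         min_coverage = 0.7) {
  paired <- dplyr::inner_join(observed[c("date", "no2")],
                              counterfactual[c("date", "no2_pred")],
                              by = "date")
  paired <- paired[stats::complete.cases(paired), , drop = FALSE]
  if (nrow(paired) < min_coverage * n_expected) {
    stop(sprintf("only %d paired complete lockdown days (< %.0f%% of %d)",
                 nrow(paired), 100 * min_coverage, n_expected),
         call. = FALSE)
  }
  cf_mean <- mean(paired$no2_pred)
  if (cf_mean <= 0) {
    stop("counterfactual mean is not positive; percent change undefined",
         call. = FALSE)
  }
  delta <- mean(paired$no2) - cf_mean
  list(delta_ml = delta, percent_change = 100 * delta / cf_mean,
       n_days_used = nrow(paired))
}

#' Compare the two attribution approaches across a city cohort
#'
#' Summarizes signed machine-learning reductions over the cohort (mean,
#' minimum and maximum magnitude with city labels, count of cities showing a
#' reduction), the squared Pearson correlation between the two approaches'
#' estimates, and the per-city discrepancy.
#'
#' @param estimates Tibble with columns `city_id`, `delta_ml`, `delta_d2d`
#'   (signed, ug/m3; negative = reduction).
#' @return List with `n_cities`, `mean_reduction`, `max_reduction`,
#'   `max_city`, `min_reduction`, `min_city` (magnitudes), `n_reduced`,
#'   `r2`, and `discrepancy` (tibble of `city_id`,
#'   `delta_ml - delta_d2d`). With fewer than 3 cities `r2` is `NA` with a
#'   warning; zero variance in either column raises an error.
#' @export
compare_approaches <- function(estimates) {
  stopifnot(all(c("city_id", "delta_ml", "delta_d2d") %in% names(estimates)))
  mag <- abs(estimates$delta_ml)
  r2 <- if (nrow(estimates) < 3) {
    warning("fewer than 3 cities: R^2 between approaches not computed",
            call. = FALSE)
    NA_real_
  } else {
    tryCatch(pearson_r2(estimates$delta_ml, estimates$delta_d2d),
             error = function(e) {
               stop("R^2 between approaches failed across ",
                    nrow(estimates), " cities: ", conditionMessage(e),
                    call. = FALSE)
             })
  }
  list(
    n_cities = nrow(estimates),
    mean_reduction = mean(mag),
    max_reduction = max(mag),
    max_city = estimates$city_id[which.max(mag)],
    min_reduction = min(mag),
    min_city = estimates$city_id[which.min(mag)],
    n_reduced = sum(estimates$delta_ml < 0),
    r2 = r2,
    discrepancy = tibble::tibble(
      city_id = estimates$city_id,
      discrepancy = estimates$delta_ml - estimates$delta_d2d
    )
  )
}
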