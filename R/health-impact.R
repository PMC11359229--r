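# Log-linear concentration-response health impact assessment: relative risk,
# attributable fraction, and avoided mortality from the lockdown-period NO2
# reductions.

#' Default concentration-response coefficients
#'
#' Log-relative-risk per ug/m3 of NO2: 0.009 for non-accidental and
#' cardiovascular mortality, 0.012 for respiratory mortality. Note the
#' per-1-ug/m3 convention: the coefficient multiplies the concentration
#' change directly (some literature reports coefficients per 10 ug/m3 —
#' rescale before overriding).
#' @export
default_betas <- c(non_accidental = 0.009, cardiovascular = 0.009,
                   respiratory = 0.012)

check_delta_c <- function(delta_c) {
  if (any(delta_c < 0)) {
    stop("`delta_c` must be the non-negative magnitude of the reduction",
         call. = FALSE)
  }
}

#' Relative risk of a concentration change
#'
#' `RR = exp(beta * delta_c)` under the log-linear concentration-response
#' model.
#'
#' @param beta Concentration-response coefficient, per ug/m3 (> 0).
#' @param delta_c Concentration reduction magnitude, ug/m3 (>= 0).
#' @return Relative risk (>= 1). Vectorized over both arguments.
#' @export
relative_risk <- function(beta, delta_c) {
  check_delta_c(delta_c)
  exp(beta * delta_c)
}

#' Attributable fraction of a concentration change
#'
#' `AF = (RR - 1) / RR = 1 - exp(-beta * delta_c)`, the share of the
#' health outcome attributable to the concentration difference.
#'
#' @inheritParams relative_risk
#' @return Fraction in \[0, 1). Vectorized.
#' @export
attributable_fraction <- function(beta, delta_c) {
  check_delta_c(delta_c)
  1 - exp(-beta * delta_c)
}

#' Cause-specific mortality parameters for one city
#'
#' Exactly one of two parameterizations must be supplied: the daily number
#' of cause-specific deaths, or a daily per-capita mortality rate `y0`
#' together with the population `pop` (in which case daily deaths =
#' `y0 * pop`).
#'
#' @param cause One of `"non_accidental"`, `"cardiovascular"`,
#'   `"respiratory"`.
#' @param beta Concentration-response coefficient per ug/m3; defaults to the
#'   cause's entry in [default_betas].
#' @param daily_deaths Deaths per day, or `NULL` when using the rate form.
#' @param y0,pop Daily per-capita mortality rate and population, or `NULL`.
#' @return List of class `cause_params`.
#' @export
cause_params <- function(cause = c("non_accidental", "cardiovascular",
                                   "respiratory"),
                         beta = NULL, daily_deaths = NULL, y0 = NULL,
                         pop = NULL) {
  cause <- match.arg(cause)
  if (is.null(beta)) beta <- default_betas[[cause]]
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  rate_form <- !is.null(y0) || !is.null(pop)
  if (rate_form && (is.null(y0) || is.null(pop))) {
    stop("rate parameterization needs both `y0` and `pop`", call. = FALSE)
  }
  if (rate_form == !is.null(daily_deaths)) {
    stop("supply exactly one of `daily_deaths` or (`y0`, `pop`)",
         call. = FALSE)
  }
  if (rate_form) {
    if (y0 < 0 || pop < 0) stop("`y0` and `pop` must be >= 0", call. = FALSE)
    daily_deaths <- y0 * pop
  } else if (daily_deaths < 0) {
    stop("`daily_deaths` must be >= 0", call. = FALSE)
  }
  structure(list(cause = cause, beta = beta, daily_deaths = daily_deaths),
            class = "cause_params")
}

#' Avoided mortality over the lockdown period
#'
#' The attributable fraction of the concentration reduction multiplied by
#' the daily cause-specific number of deaths and the number of lockdown
#' days.
#'
#' @param params A [cause_params()] object.
#' @param delta_c Concentration reduction magnitude, ug/m3.
#' @param n_days Number of days in the lockdown window (default 56,
#'   23 January - 18 March 2020 inclusive).
#' @return Avoided number of deaths (persons).
#' @export
avoided_mortality <- function(params, delta_c, n_days = 56) {
  stopifnot(inherits(params, "cause_params"))
  if (n_days < 1) stop("`n_days` must be >= 1", call. = FALSE)
  attributable_fraction(params$beta, delta_c) * params$daily_deaths * n_days
}

#' Cohort health burden from the estimated reductions
#'
#' Applies the concentration-response chain per city and cause. Cities whose
#' machine-learning estimate shows no reduction (`delta_ml >= 0`) contribute
#' zero. Every city must have parameters for all three causes.
#'
#' @param estimates Tibble with `city_id`, `delta_ml` (signed).
#' @param params_table Tibble with columns `city_id`, `cause`,
#'   `daily_deaths` and optionally `beta` (defaults to [default_betas] by
#'   cause).
#' @param n_days Lockdown length in days.
#' @return List with `burdens` (tibble of `city_id`, `cause`, `delta_c`,
#'   `rr`, `af`, `avoided_deaths`) and `totals` (tibble of `cause`,
#'   `avoided_deaths`).
#' @export
cohort_burden <- function(estimates, params_table, n_days = 56) {
  causes <- names(default_betas)
  need <- tidyr::expand_grid(city_id = estimates$city_id, cause = causes)
  have <- params_table[c("city_id", "cause")]
  gap <- dplyr::anti_join(need, have, by = c("city_id", "cause"))
  if (nrow(gap) > 0) {
    stop("missing mortality parameters for ",
         paste(paste0(gap$city_id, "/", gap$cause), collapse = ", "),
         call. = FALSE)
  }
  if (!"beta" %in% names(params_table)) {
    params_table$beta <- default_betas[params_table$cause]
  }
  joined <- dplyr::inner_join(estimates[c("city_id", "delta_ml")],
                              params_table, by = "city_id")
  joined$delta_c <- pmax(0, -joined$delta_ml)
  burdens <- tibble::tibble(
    city_id = joined$city_id,
    cause = joined$cause,
    delta_c = joined$delta_c,
    rr = relative_risk(joined$beta, joined$delta_c),
    af = attributable_fraction(joined$beta, joined$delta_c),
    avoided_deaths = attributable_fraction(joined$beta, joined$delta_c) *
      joined$daily_deaths * n_days
  )
  totals <- dplyr::summarise(dplyr::group_by(burdens, .data$cause),
                             avoided_deaths = sum(.data$avoided_deaths),
                             .groups = "drop")
  list(burdens = burdens, totals = totals)
}
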