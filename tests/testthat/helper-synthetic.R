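# Shared synthetic configurations.
#
# The "calendar-only" configuration removes every structural feature the
# default model cannot represent exactly (meteorology, weekday cycle, year
# trend, the sharp holiday dip), so the generated series is a smooth
# deterministic function of the model's own predictors: ideal for exact
# identifiability checks of the attribution plumbing.
calendar_only_config <- function(seed = 7, lockdown_effect = 16, ...) {
  synthetic_city_config(
    seed = seed, noise_sd = 0, missing_fraction = 0,
    year_trend = 0, weekday_effects = rep(0, 7), holiday_dip = 0,
    met_coefficients = list(wind_speed = 0, temperature = 0,
                            relative_humidity = 0, wind_direction = 0),
    lockdown_effect = lockdown_effect, ...
  )
}

# Noiseless but with full meteorological dependence (dip and weekday still
# off): deterministic given the weather, used for model-skill checks.
smooth_met_config <- function(seed = 11, lockdown_effect = 16, ...) {
  synthetic_city_config(
    seed = seed, noise_sd = 0, missing_fraction = 0,
    year_trend = 0, weekday_effects = rep(0, 7), holiday_dip = 0,
    lockdown_effect = lockdown_effect, ...
  )
}

# Small forest for unit tests where statistical precision is not the point.
quick_spec <- function(seed = 42L) model_spec(n_trees = 120, m_try = 4,
                                              random_seed = seed)

# Independent re-statement of the generator's structural mean for flat-met
# configurations, used as an oracle (kept deliberately separate from the
# package internals).
oracle_structural_mean <- function(config, dates,
                                   cal = holiday_calendar()) {
  doy <- as.POSIXlt(dates)$yday + 1
  wd <- ((as.POSIXlt(dates)$wday + 6) %% 7) + 1
  season <- as.integer(format(dates, "%Y")) +
    as.integer(format(dates, "%m") == "12")
  dl <- as.integer(dates - unclass(cal)[as.character(season)])
  config$base_level +
    config$year_trend * (season - 2017) +
    config$weekday_effects[wd] +
    config$seasonal_amplitude * cos(2 * pi * (doy - 1) / 365.25) -
    config$holiday_dip * exp(-0.5 * (dl / config$holiday_halfwidth)^2)
}
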