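# Period means, the difference-to-difference arithmetic, the
# observed-minus-counterfactual estimator, and the cohort comparison.

constant_series <- function(value = 40) {
  dates <- do.call(c, lapply(2017:2020, function(y) {
    seq(as.Date(sprintf("%d-12-01", y - 1)), as.Date(sprintf("%d-04-30", y)),
        by = "day")
  }))
  tibble::tibble(city_id = "const", date = dates, no2 = value,
                 wind_speed = 3, wind_direction = 180, temperature = 5,
                 relative_humidity = 60)
}

test_that("the default period scheme matches the study timeline", {
  scheme <- period_scheme()
  expect_length(period_dates(scheme, "lockdown"), 56)
  expect_identical(scheme$pre_lockdown[1], as.Date("2019-12-01"))
  expect_identical(scheme$post_lockdown[2], as.Date("2020-04-30"))
  expect_error(period_scheme(pre_end = "2020-01-20"), "contiguous")
})

test_that("period means handle constants, shifts, and coverage", {
  means <- period_means(constant_series(40))
  expect_equal(unlist(means), stats::setNames(rep(40, 6), names(unlist(means))))

  shifted <- constant_series(40)
  shifted$no2[shifted$date >= as.Date("2019-12-01")] <- 45
  m2 <- period_means(shifted)
  for (p in c("blp", "dlp", "alp")) {
    expect_equal(m2[[paste0("c2020_", p)]] - m2[[paste0("chist_", p)]], 5)
  }

  sparse <- constant_series(40)
  dlp <- period_dates(period_scheme(), "lockdown")
  sparse$no2[sparse$date %in% dlp[1:30]] <- NA
  expect_error(period_means(sparse), "2020 DLP")
})

test_that("noiseless generator means match the analytic structural means", {
  cfg <- synthetic_city_config(
    seed = 3, noise_sd = 0, missing_fraction = 0, lockdown_effect = 10,
    met_coefficients = list(wind_speed = 0, temperature = 0,
                            relative_humidity = 0, wind_direction = 0)
  )
  series <- generate_city(cfg)
  means <- period_means(series)
  scheme <- period_scheme()
  dlp <- period_dates(scheme, "lockdown")
  expect_equal(means$c2020_dlp,
               mean(oracle_structural_mean(cfg, dlp)) - 10)
  blp <- period_dates(scheme, "pre_lockdown")
  expect_equal(means$c2020_blp, mean(oracle_structural_mean(cfg, blp)))
})

test_that("difference-to-difference arithmetic is exact and linear", {
  id <- list(c2020_blp = 40, c2020_dlp = 40, c2020_alp = 40,
             chist_blp = 40, chist_dlp = 40, chist_alp = 40)
  expect_equal(unlist(diff_to_diff(id)), c(cd_blp = 0, cd_dlp = 0,
                                           cd_alp = 0, cadj_d_dlp = 0))

  m <- list(c2020_blp = 40, c2020_dlp = 25, c2020_alp = 45,
            chist_blp = 50, chist_dlp = 50, chist_alp = 50)
  d <- diff_to_diff(m)
  expect_equal(unlist(d), c(cd_blp = -10, cd_dlp = -25, cd_alp = -5,
                            cadj_d_dlp = -15))

  k <- 2.5
  dk <- diff_to_diff(lapply(m, `*`, k))
  expect_equal(unlist(dk), k * unlist(d))
})

test_that("the machine-learning estimator matches hand arithmetic", {
  dates <- seq(as.Date("2020-01-23"), by = "day", length.out = 56)
  obs <- tibble::tibble(date = dates, no2 = 29)
  cf <- tibble::tibble(date = dates, no2_pred = 50)
  got <- ml_reduction(obs, cf)
  expect_equal(got$delta_ml, -21)
  expect_equal(got$percent_change, -42)
  expect_identical(got$n_days_used, 56L)

  same <- ml_reduction(obs, tibble::tibble(date = dates, no2_pred = 29))
  expect_equal(same$delta_ml, 0)
  expect_equal(same$percent_change, 0)

  expect_error(ml_reduction(obs[1:30, ], cf), "paired complete")
  expect_error(ml_reduction(obs, tibble::tibble(date = dates, no2_pred = 0)),
               "not positive")
})

test_that("noiseless pipeline attribution recovers the injected effect", {
  res <- attribute_city(generate_city(calendar_only_config(lockdown_effect = 16)))
  expect_lt(abs(res$estimate$delta_ml + 16), 0.5)
  # with the sharp holiday depression restored, tree smoothing costs some
  # accuracy but the estimate stays close; calendar-aligned differencing
  # misses by more because the holiday falls on different dates each winter
  cfg_dip <- calendar_only_config(lockdown_effect = 16)
  cfg_dip$holiday_dip <- 12
  res_dip <- attribute_city(generate_city(cfg_dip))
  expect_lt(abs(res_dip$estimate$delta_ml + 16), 1.5)
  expect_gt(abs(res_dip$estimate$delta_d2d + 16),
            abs(res_dip$estimate$delta_ml + 16))
})

test_that("cohort comparison summarizes magnitudes and correlation", {
  est <- tibble::tibble(
    city_id = c("A", "B", "C", "D"),
    delta_ml = c(-10, -20, -5, -15),
    delta_d2d = c(-8, -15, -6, -12)
  )
  cmp <- compare_approaches(est)
  expect_identical(cmp$n_cities, 4L)
  expect_equal(cmp$mean_reduction, 12.5)
  expect_identical(cmp$max_city, "B")
  expect_identical(cmp$min_city, "C")
  expect_identical(cmp$n_reduced, 4L)
  expect_equal(cmp$r2, pearson_r2(est$delta_ml, est$delta_d2d))
  expect_equal(cmp$discrepancy$discrepancy, est$delta_ml - est$delta_d2d)

  # identical columns correlate perfectly
  est2 <- est
  est2$delta_d2d <- est2$delta_ml
  expect_equal(compare_approaches(est2)$r2, 1)

  # constant estimates: correlation undefined, surfaced with context
  flat <- est
  flat$delta_ml <- -10
  expect_error(compare_approaches(flat), "across 4 cities")

  expect_warning(cmp2 <- compare_approaches(est[1:2, ]), "fewer than 3")
  expect_true(is.na(cmp2$r2))
  expect_equal(cmp2$mean_reduction, 15)
})
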