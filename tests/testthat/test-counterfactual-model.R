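# Business-as-usual random-forest modelling: spec validation, importance
# construction oracle, prediction fidelity and the leave-one-winter-out
# protocol.

test_that("model specification enforces its bounds", {
  expect_error(model_spec(m_try = 8), "between 1 and 7")
  expect_error(model_spec(m_try = 0), "between 1 and 7")
  expect_error(model_spec(n_trees = 0), "n_trees")
  spec <- model_spec()
  expect_identical(spec$n_trees, 500L)
  expect_identical(spec$m_try, 4L)
  expect_length(spec$predictors, 7)
})

test_that("wind speed dominates importance when it is the only driver", {
  cfg <- synthetic_city_config(
    seed = 6, noise_sd = 0, missing_fraction = 0, year_trend = 0,
    weekday_effects = rep(0, 7), seasonal_amplitude = 0, holiday_dip = 0,
    met_coefficients = list(wind_speed = 30, temperature = 0,
                            relative_humidity = 0, wind_direction = 0),
    lockdown_effect = 0
  )
  feats <- build_features(generate_city(cfg))
  model <- fit_city_model(feats[feats$year %in% 2017:2019, ], quick_spec())
  imp <- model$variable_importance
  expect_identical(names(which.max(imp)), "wind_speed")
  expect_true(all(imp >= 0))
  expect_equal(sum(imp), 100, tolerance = 1e-8)
})

test_that("fitting is deterministic and stable under row duplication", {
  feats <- build_features(generate_city(synthetic_city_config(seed = 8)))
  train <- feats[feats$year %in% 2017:2019, ]
  m1 <- fit_city_model(train, quick_spec())
  m2 <- fit_city_model(train, quick_spec())
  expect_identical(m1$variable_importance, m2$variable_importance)
  p1 <- predict_counterfactual(m1, feats[feats$year == 2020L, ])
  p2 <- predict_counterfactual(m2, feats[feats$year == 2020L, ])
  expect_identical(p1, p2)

  # duplicating every row changes the bootstrap draws but must not reshuffle
  # the importance structure: the lead variable is stable and near-tied
  # variables may at most swap locally
  doubled <- dplyr::bind_rows(train, train)
  m3 <- fit_city_model(doubled, quick_spec())
  expect_identical(names(which.max(m1$variable_importance)),
                   names(which.max(m3$variable_importance)))
  shared <- names(m1$variable_importance)
  expect_gt(stats::cor(rank(m1$variable_importance[shared]),
                       rank(m3$variable_importance[shared]),
                       method = "spearman"), 0.9)
})

test_that("training-row floor and missing columns are reported", {
  feats <- build_features(generate_city(synthetic_city_config(seed = 8)))
  train <- feats[feats$year %in% 2017:2019, ]
  expect_error(fit_city_model(train[1:50, ], quick_spec()), "floor of 100")
  model <- fit_city_model(train, quick_spec())
  expect_error(predict_counterfactual(model, train[, -which(names(train) ==
                                                              "wind_speed")]),
               "wind_speed")
})

test_that("predictions are reproducible per row and empty-safe", {
  feats <- build_features(generate_city(smooth_met_config(seed = 14)))
  train <- feats[feats$year %in% 2017:2019, ]
  model <- fit_city_model(train, quick_spec())
  rows <- feats[feats$year == 2020L, ][1:5, ]
  twice <- dplyr::bind_rows(rows, rows)
  p <- predict_counterfactual(model, twice)
  expect_identical(p$no2_pred[1:5], p$no2_pred[6:10])
  empty <- predict_counterfactual(model, feats[0, ])
  expect_identical(nrow(empty), 0L)
  expect_true(all(p$no2_pred >= 0))
})

test_that("in-bag predictions track a smooth noiseless process", {
  feats <- build_features(generate_city(calendar_only_config(seed = 14)))
  train <- feats[feats$year %in% 2017:2019, ]
  model <- fit_city_model(train, model_spec(random_seed = 14))
  pred <- predict_counterfactual(model, train)
  err <- abs(pred$no2_pred - train$no2)
  expect_gte(mean(err <= 1), 0.95)
})

test_that("cross-validation requires and produces exactly three folds", {
  feats <- build_features(generate_city(smooth_met_config(seed = 11)))
  ref <- feats[feats$year %in% 2017:2019, ]
  cv <- cross_validate_by_year(ref, quick_spec())
  expect_identical(nrow(cv), 3L)
  expect_setequal(cv$held_out_year, 2017:2019)
  expect_error(cross_validate_by_year(feats, quick_spec()), "exactly 3")
  # a pure-noise response has no held-out skill
  null_ref <- ref
  null_ref$no2 <- withr::with_seed(1, runif(nrow(ref), 20, 60))
  cv_null <- cross_validate_by_year(null_ref, quick_spec())
  expect_true(all(cv_null$ioa < 0.4))
})

test_that("grid tuning returns the IOA-maximizing specification", {
  feats <- build_features(generate_city(smooth_met_config(seed = 11)))
  ref <- feats[feats$year %in% 2017:2019, ]
  one <- tune_model_spec(ref, n_trees_grid = 60, m_try_grid = 4)
  expect_identical(one$best_spec$n_trees, 60L)
  expect_identical(one$best_spec$m_try, 4L)
  expect_identical(nrow(one$report), 1L)
  small <- tune_model_spec(ref, n_trees_grid = c(40, 80), m_try_grid = c(2, 4))
  expect_identical(nrow(small$report), 4L)
  best <- small$report[which.max(small$report$mean_ioa), ]
  expect_identical(small$best_spec$n_trees, as.integer(best$n_trees))
})

test_that("a pure-noise predictor barely moves held-out skill", {
  feats <- build_features(generate_city(smooth_met_config(seed = 11)))
  ref <- feats[feats$year %in% 2017:2019, ]
  base_cv <- cross_validate_by_year(ref, quick_spec())
  ref$junk <- withr::with_seed(2, rnorm(nrow(ref)))
  spec8 <- model_spec(n_trees = 120, m_try = 4, random_seed = 42,
                      predictors = c(default_predictors, "junk"))
  junk_cv <- cross_validate_by_year(ref, spec8)
  expect_lt(max(abs(junk_cv$ioa - base_cv$ioa)), 0.05)
})
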