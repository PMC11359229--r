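# Per-city business-as-usual modelling: a random forest trained on the
# reference winters predicts what NO2 would have been in the 2019-20 winter
# under normal emissions, given the calendar and the weather that actually
# occurred.

#' Canonical predictor set
#'
#' The seven predictors carried into the default model: the winter-season
#' label, day of year, days relative to the Lunar New Year holiday, and the
#' four meteorological variables. The feature table also carries a `weekday`
#' column; it is not part of the default predictor set (the importance
#' accounting treats the weekly cycle as absorbed by the other calendar
#' terms) but can be added via `model_spec(predictors = ...)`.
#' @export
default_predictors <- c("year", "day_julian", "day_lunar", "wind_speed",
                        "wind_direction", "temperature", "relative_humidity")

#' Random-forest model specification
#'
#' @param n_trees Number of trees (default 500).
#' @param m_try Candidate predictors per split (default 4); must lie between
#'   1 and the number of predictors.
#' @param random_seed Seed making fit and prediction reproducible.
#' @param predictors Character vector of predictor column names.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(n_trees = 500, m_try = 4, random_seed = 1L,
                       predictors = default_predictors) {
  if (!is.numeric(n_trees) || n_trees < 1) {
    stop("`n_trees` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(m_try) || m_try < 1 || m_try > length(predictors)) {
    stop("`m_try` must be between 1 and ", length(predictors),
         " (the number of predictors)", call. = FALSE)
  }
  structure(list(n_trees = as.integer(n_trees), m_try = as.integer(m_try),
                 random_seed = as.integer(random_seed),
                 predictors = predictors),
            class = "model_spec")
}

complete_rows <- function(features, predictors, need_response = TRUE) {
  cols <- if (need_response) c(predictors, "no2") else predictors
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  features[stats::complete.cases(features[cols]), , drop = FALSE]
}

#' Fit one city's business-as-usual model
#'
#' Trains a random forest of `spec$n_trees` trees on the complete rows of
#' `features` (which should be restricted to the reference winters).
#' Variable importance (node-purity based) is normalized to percentage
#' shares summing to 100.
#'
#' @param features Feature table from [build_features()], restricted to the
#'   training winters.
#' @param spec A [model_spec()].
#' @param min_rows Minimum number of complete training rows (default 100).
#' @return A list of class `city_model` with fields `city_id`, `spec`,
#'   `training_rows`, `variable_importance` (named percentages) and the
#'   fitted forest.
#' @export
fit_city_model <- function(features, spec = model_spec(), min_rows = 100) {
  train <- complete_rows(features, spec$predictors)
  if (nrow(train) < min_rows) {
    stop("too few complete training rows (", nrow(train), " < floor of ",
         min_rows, ")", call. = FALSE)
  }
  forest <- withr::with_seed(spec$random_seed, {
    randomForest::randomForest(
      x = as.data.frame(train[spec$predictors]),
      y = train$no2,
      ntree = spec$n_trees,
      mtry = spec$m_try
    )
  })
  imp <- randomForest::importance(forest, type = 2)[, 1]
  structure(
    list(city_id = if ("city_id" %in% names(train)) train$city_id[1] else NA,
         spec = spec,
         training_rows = nrow(train),
         variable_importance = 100 * imp / sum(imp),
         forest = forest),
    class = "city_model"
  )
}

#' @export
print.city_model <- function(x, ...) {
  cat("Business-as-usual NO2 model for", x$city_id, "\n")
  cat("  trees:", x$spec$n_trees, " mtry:", x$spec$m_try,
      " training rows:", x$training_rows, "\n")
  cat("  variable importance (%):\n")
  imp <- sort(x$variable_importance, decreasing = TRUE)
  for (v in names(imp)) cat(sprintf("    %-18s %5.1f\n", v, imp[v]))
  invisible(x)
}

#' Predict counterfactual (business-as-usual) concentrations
#'
#' One prediction per complete row of the supplied feature table; rows with
#' any missing predictor are skipped. Predictions are floored at zero.
#'
#' @param model A fitted [fit_city_model()] object.
#' @param features Feature table for the days to predict (response not
#'   required).
#' @return Tibble with `date` and `no2_pred` for the complete rows.
#' @export
predict_counterfactual <- function(model, features) {
  rows <- complete_rows(features, model$spec$predictors,
                        need_response = FALSE)
  if (nrow(rows) == 0) {
    return(tibble::tibble(date = as.Date(character()),
                          no2_pred = numeric()))
  }
  pred <- withr::with_seed(model$spec$random_seed, {
    as.numeric(stats::predict(model$forest,
                              as.data.frame(rows[model$spec$predictors])))
  })
  tibble::tibble(date = rows$date, no2_pred = pmax(0, pred))
}

#' Leave-one-winter-out cross-validation
#'
#' With exactly three reference winters present, trains on each pair of
#' winters and scores on the held-out one with the full metric suite.
#'
#' @param features Feature table restricted to the reference winters.
#' @param spec A [model_spec()].
#' @param min_rows Training-row floor passed to [fit_city_model()].
#' @return Tibble with one row per fold: `held_out_year` plus the
#'   [error_metrics()] columns.
#' @export
cross_validate_by_year <- function(features, spec = model_spec(),
                                   min_rows = 100) {
  years <- sort(unique(features$year))
  if (length(years) != 3) {
    stop("cross-validation requires exactly 3 reference winters, found ",
         length(years), call. = FALSE)
  }
  purrr::map_dfr(years, function(y) {
    fold_model <- fit_city_model(features[features$year != y, ], spec,
                                 min_rows = min_rows)
    held <- complete_rows(features[features$year == y, ], spec$predictors)
    pred <- predict_counterfactual(fold_model, held)
    dplyr::bind_cols(tibble::tibble(held_out_year = y),
                     error_metrics(held$no2, pred$no2_pred))
  })
}

#' Grid search over forest size and split width
#'
#' Evaluates every (n_trees, m_try) combination by mean cross-validated
#' index of agreement and returns the best specification; ties are broken by
#' the smaller `n_trees`, then the smaller `m_try`. The default grid is the
#' 5 x 6 grid of {50, 100, 200, 500, 1000} trees by mtry 2..7.
#'
#' @param features Feature table restricted to the reference winters.
#' @param n_trees_grid,m_try_grid Grid axes.
#' @param random_seed Seed used for every candidate fit.
#' @param min_rows Training-row floor.
#' @return List with `best_spec` and `report` (one row per combination with
#'   its mean held-out IOA).
#' @export
tune_model_spec <- function(features,
                            n_trees_grid = c(50, 100, 200, 500, 1000),
                            m_try_grid = 2:7,
                            random_seed = 1L,
                            min_rows = 100) {
  grid <- expand.grid(n_trees = n_trees_grid, m_try = m_try_grid)
  if (nrow(grid) == 0) stop("empty tuning grid", call. = FALSE)
  report <- purrr::pmap_dfr(grid, function(n_trees, m_try) {
    spec <- model_spec(n_trees, m_try, random_seed)
    cv <- cross_validate_by_year(features, spec, min_rows = min_rows)
    tibble::tibble(n_trees = n_trees, m_try = m_try,
                   mean_ioa = mean(cv$ioa))
  })
  ranked <- report[order(-report$mean_ioa, report$n_trees, report$m_try), ]
  list(best_spec = model_spec(ranked$n_trees[1], ranked$m_try[1],
                              random_seed),
       report = report)
}
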