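# Statistical evaluation suite used throughout the pipeline: Willmott's index
# of agreement plus the bias/error family (MBE, MAE, RMSE and their
# observed-mean-normalized forms) and the squared Pearson correlation.

drop_incomplete_pairs <- function(obs, pred) {
  if (length(obs) != length(pred)) {
    stop("`obs` and `pred` must have equal length (", length(obs), " vs ",
         length(pred), ")", call. = FALSE)
  }
  keep <- is.finite(obs) & is.finite(pred)
  list(obs = obs[keep], pred = pred[keep], n = sum(keep))
}

#' Willmott's index of agreement
#'
#' Computes the original (quadratic) index of agreement
#' \eqn{d = 1 - \sum (P_i - O_i)^2 / \sum (|P_i - \bar O| + |O_i - \bar O|)^2},
#' the headline skill score in air-quality model evaluation. A value of 1
#' means perfect agreement; a model that predicts the observed mean for every
#' day scores exactly 0, and worse-than-mean predictions go negative.
#'
#' Unlike the squared correlation, the index penalizes additive and
#' proportional bias: an anti-correlated prediction can have \eqn{R^2 = 1}
#' but a very low index of agreement.
#'
#' @param obs Numeric vector of observations. Pairs with missing values in
#'   either vector are dropped.
#' @param pred Numeric vector of predictions, same length as `obs`.
#' @return A single number, at most 1.
#' @examples
#' index_of_agreement(c(1, 2, 3), c(1, 2, 4))
#' index_of_agreement(c(1, 2, 3), c(2, 2, 2)) # constant at the mean -> 0
#' @export
index_of_agreement <- function(obs, pred) {
  p <- drop_incomplete_pairs(obs, pred)
  if (p$n < 2) stop("need at least 2 complete (obs, pred) pairs", call. = FALSE)
  o_bar <- mean(p$obs)
  if (stats::var(p$obs) == 0) {
    # constant observations carry no variability to agree with; only a
    # prediction identical to them is scoreable (perfect agreement)
    if (all(p$pred == p$obs)) return(1)
    stop("index of agreement undefined: observations are constant but ",
         "predictions differ from them", call. = FALSE)
  }
  denom <- sum((abs(p$pred - o_bar) + abs(p$obs - o_bar))^2)
  1 - sum((p$pred - p$obs)^2) / denom
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values are
#'   dropped. At least 3 complete pairs and nonzero variance in both vectors
#'   are required.
#' @return The square of the Pearson product-moment correlation, in \[0, 1\].
#' @export
pearson_r2 <- function(x, y) {
  p <- drop_incomplete_pairs(x, y)
  if (p$n < 3) stop("need at least 3 complete pairs for R^2", call. = FALSE)
  if (stats::var(p$obs) == 0 || stats::var(p$pred) == 0) {
    stop("R^2 undefined: zero variance in input", call. = FALSE)
  }
  stats::cor(p$obs, p$pred)^2
}

#' Full evaluation-metric report for paired observations and predictions
#'
#' Returns a one-row tibble with the count of complete pairs and the metric
#' suite: mean bias error (MBE), mean absolute error (MAE), root mean squared
#' error (RMSE), their observed-mean-normalized counterparts in percent
#' (NMBE, NME, NRMSE), the squared Pearson correlation and the index of
#' agreement. NME and NMAE denote the same quantity (MAE over the observed
#' mean) and only the NME label is reported.
#'
#' @inheritParams index_of_agreement
#' @return Tibble with columns `n`, `mbe`, `mae`, `rmse`, `nmbe`, `nme`,
#'   `nrmse` (percent), `r2`, `ioa`. Errors are in the units of the inputs.
#' @export
error_metrics <- function(obs, pred) {
  p <- drop_incomplete_pairs(obs, pred)
  if (p$n < 2) stop("need at least 2 complete (obs, pred) pairs", call. = FALSE)
  resid <- p$pred - p$obs
  o_mean <- mean(p$obs)
  if (o_mean == 0) {
    stop("normalized metrics undefined: mean of observations is 0",
         call. = FALSE)
  }
  mbe <- mean(resid)
  mae <- mean(abs(resid))
  rmse <- sqrt(mean(resid^2))
  r2 <- if (stats::var(p$obs) > 0 && stats::var(p$pred) > 0) {
    stats::cor(p$obs, p$pred)^2
  } else {
    NA_real_
  }
  tibble::tibble(
    n = p$n,
    mbe = mbe,
    mae = mae,
    rmse = rmse,
    nmbe = 100 * mbe / o_mean,
    nme = 100 * mae / o_mean,
    nrmse = 100 * rmse / o_mean,
    r2 = r2,
    ioa = index_of_agreement(p$obs, p$pred)
  )
}
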