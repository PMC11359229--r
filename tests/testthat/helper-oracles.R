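# Deliberately naive loop implementation of the metric suite, the
# independent oracle the vectorized implementation is checked against.
brute_force_metrics <- function(obs, pred) {
  n <- length(obs)
  s_resid <- 0; s_abs <- 0; s_sq <- 0; s_obs <- 0
  for (i in seq_len(n)) {
    s_resid <- s_resid + (pred[i] - obs[i])
    s_abs <- s_abs + abs(pred[i] - obs[i])
    s_sq <- s_sq + (pred[i] - obs[i])^2
    s_obs <- s_obs + obs[i]
  }
  o_bar <- s_obs / n
  denom <- 0
  for (i in seq_len(n)) {
    denom <- denom + (abs(pred[i] - o_bar) + abs(obs[i] - o_bar))^2
  }
  list(mbe = s_resid / n, mae = s_abs / n, rmse = sqrt(s_sq / n),
       nmbe = 100 * (s_resid / n) / o_bar, nme = 100 * (s_abs / n) / o_bar,
       nrmse = 100 * sqrt(s_sq / n) / o_bar, ioa = 1 - s_sq / denom)
}
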