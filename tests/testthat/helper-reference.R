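# Independent reference implementations used as oracles.

# Closed-form OLS slope: sum((x - xbar)(y - ybar)) / sum((x - xbar)^2)
ols_slope_closed_form <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Brute-force peak detector: exhaustive local-maxima enumeration plus exact
# greedy refractory suppression via repeated scans over the remaining
# candidates. Deliberately naive (O(n^2)); mirrors the documented contract,
# not the package's code path.
brute_force_peaks <- function(x, fs, f_dom) {
  rng <- range(x)
  xn <- (x - rng[1]) / (rng[2] - rng[1])
  thr <- mean(xn)
  min_dist <- max(1, round(0.7 * fs / f_dom))
  cand <- c()
  for (i in seq_along(xn)) {
    if (i > 1 && i < length(xn) &&
        xn[i] > xn[i - 1] && xn[i] > xn[i + 1] && xn[i] > thr)
      cand <- c(cand, i)
  }
  kept <- c()
  while (length(cand) > 0) {
    best <- cand[1]
    for (j in cand) if (xn[j] > xn[best]) best <- j  # ties keep earliest
    kept <- c(kept, best)
    remaining <- c()
    for (j in cand) if (abs(j - best) >= min_dist) remaining <- c(remaining, j)
    cand <- remaining
  }
  sort(kept)
}

# Shorthand for a deterministic noise-free simulation config in tests;
# any argument can still be overridden.
quiet_config <- function(...) {
  args <- utils::modifyList(list(noise_sd = 0, ecg_noise_sd = 0, hrv_sd = 0,
                                 baseline_drift_amp = 0), list(...))
  do.call(sim_config, args)
}
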