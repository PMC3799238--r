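# Shared fixture builders. Everything is generated in code; seeds are fixed
# by the caller so tests are reproducible.

poisson_train <- function(rate_hz, span = c(0, 300), unit_id = "u", seed = NULL) {
  gen <- function() {
    n <- stats::rpois(1, rate_hz * diff(span))
    spike_train(sort(stats::runif(n, span[1], span[2])), span = span,
                unit_id = unit_id)
  }
  if (is.null(seed)) gen() else iedflow:::with_seed(seed, gen())
}

regular_events <- function(from = 5, to = 295, by = 2) {
  event_set(peak_time = seq(from, to, by = by))
}

# brute-force O(n^2) cross-correlogram oracle (half-open 1-ms bins)
ccg_oracle <- function(a, b, max_lag_ms = 100, bin_ms = 1) {
  d <- as.vector(outer(b$times, a$times, "-")) * 1000
  nb <- as.integer(2 * max_lag_ms / bin_ms)
  d <- d[d >= -max_lag_ms & d < max_lag_ms]
  tabulate(floor((d + max_lag_ms) / bin_ms) + 1L, nbins = nb)
}

# brute-force coincidence oracle: ordered cross pairs, same event,
# |dt| <= window/2, binned at the earlier latency
coincidence_oracle <- function(ra, rb, window_ms = 5, bin_ms = 10) {
  hw <- ra$halfwidth_ms
  nb <- as.integer(2 * hw / bin_ms)
  cnt <- integer(nb)
  for (e in seq_along(ra$latencies)) {
    la <- ra$latencies[[e]]; lb <- rb$latencies[[e]]
    for (x in la) {
      hits <- lb[abs(lb - x) <= window_ms / 2]
      for (y in hits) {
        k <- floor((min(x, y) + hw) / bin_ms) + 1L
        if (k >= 1 && k <= nb) cnt[k] <- cnt[k] + 1L
      }
    }
  }
  cnt
}
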