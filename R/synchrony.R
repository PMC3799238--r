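# Pairwise spike synchronization: jitter-surrogate cross-correlograms and
# dither-surrogate coincidence analysis.
#
# Null model: both trains are jittered/dithered independently (symmetric
# null); a one-train mode is available. Per-pair RNG streams are derived
# from a master seed plus the pair id, so results are independent of the
# order in which pairs are analysed.

#' Cross-correlogram of two spike trains
#'
#' Counts of ordered lags `t_b - t_a` in half-open 1-ms bins covering
#' `[-max_lag, +max_lag)`.
#'
#' @param a,b [spike_train] objects over a common span.
#' @param max_lag_ms maximal lag (ms).
#' @param bin_ms bin width (ms).
#' @param min_spikes pair eligibility: each train needs more than this many
#'   spikes (default 100).
#' @return A `cross_correlogram`: data frame `lag_ms` (bin left edge, ms),
#'   `count`, with attributes `n_ref`, `n_tgt`, `bin_ms`.
#' @export
cross_correlogram <- function(a, b, max_lag_ms = 100, bin_ms = 1,
                              min_spikes = 100) {
  if (length(a$times) <= min_spikes || length(b$times) <= min_spikes)
    stop_fmt("cross_correlogram: pair %s/%s ineligible (need > %d spikes each, have %d/%d)",
             a$unit_id, b$unit_id, min_spikes, length(a$times), length(b$times))
  max_lag <- max_lag_ms / 1000; bin_w <- bin_ms / 1000
  counts <- .ccg_count_cpp(a$times, b$times, max_lag, bin_w)
  nb <- length(counts)
  df <- data.frame(lag_ms = -max_lag_ms + bin_ms * (seq_len(nb) - 1L),
                   count = counts)
  structure(df, class = c("cross_correlogram", "data.frame"),
            n_ref = length(a$times), n_tgt = length(b$times),
            bin_ms = bin_ms, max_lag_ms = max_lag_ms)
}

#' Jitter-surrogate confidence band for a cross-correlogram
#'
#' Each surrogate adds an independent `N(0, sd_ms)` offset to every spike
#' of both trains (or of `b` only in one-train mode), re-sorts, and
#' recomputes the correlogram; per-bin bounds are empirical quantiles
#' (linear interpolation) at the stated coverage.
#'
#' @inheritParams cross_correlogram
#' @param sd_ms jitter SD in ms (default 50).
#' @param n number of surrogates (default 1000).
#' @param coverage central coverage of the band (default 0.99).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @param both logical: jitter both trains (default) or only `b`.
#' @return A `surrogate_band`: data frame `lag_ms`, `lower`, `upper` with
#'   attributes `n_surrogates`, `coverage`, `seed`.
#' @export
jitter_band <- function(a, b, sd_ms = 50, n = 1000, coverage = 0.99,
                        seed = 1L, max_lag_ms = 100, bin_ms = 1,
                        min_spikes = 100, both = TRUE) {
  if (length(a$times) <= min_spikes || length(b$times) <= min_spikes)
    stop_fmt("jitter_band: pair ineligible (need > %d spikes each)", min_spikes)
  max_lag <- max_lag_ms / 1000; bin_w <- bin_ms / 1000
  surr <- with_seed(seed, {
    if (both) {
      .ccg_jitter_surr_cpp(a$times, b$times, max_lag, bin_w, sd_ms / 1000, n)
    } else {
      # jitter only b: emulate by sd 0 on a
      m <- matrix(0L, as.integer(2 * max_lag_ms / bin_ms), n)
      for (s in seq_len(n)) {
        jb <- sort(b$times + stats::rnorm(length(b$times), 0, sd_ms / 1000))
        m[, s] <- .ccg_count_cpp(a$times, jb, max_lag, bin_w)
      }
      m
    }
  })
  alpha <- (1 - coverage) / 2
  lower <- apply(surr, 1, stats::quantile, probs = alpha, names = FALSE)
  upper <- apply(surr, 1, stats::quantile, probs = 1 - alpha, names = FALSE)
  nb <- nrow(surr)
  df <- data.frame(lag_ms = -max_lag_ms + bin_ms * (seq_len(nb) - 1L),
                   lower = lower, upper = upper)
  structure(df, class = c("surrogate_band", "data.frame"),
            n_surrogates = n, coverage = coverage, seed = seed,
            mean_count = rowMeans(surr))
}

#' Significance of a cross-correlogram against its jitter band
#'
#' Significant iff at least one bin with `|lag|` in `interval_ms`
#' (default `[1.5, 30]` ms, judged at bin centres) has an observed count
#' strictly above the band's upper bound. Also reports, as a separate
#' descriptive flag, whether any significant bin lies within +/-25 ms of
#' the origin.
#'
#' @param ccg a [cross_correlogram].
#' @param band a [jitter_band] built from the same pair.
#' @param interval_ms absolute-lag interval defining the decision bins.
#' @return A list: `significant`, `significant_bins` (lag_ms of exceeding
#'   bins), `peak_within_25ms`.
#' @export
ccg_significant <- function(ccg, band, interval_ms = c(1.5, 30)) {
  stopifnot(nrow(ccg) == nrow(band))
  centers <- ccg$lag_ms + attr(ccg, "bin_ms") / 2
  in_int <- abs(centers) >= interval_ms[1] & abs(centers) <= interval_ms[2]
  exceed <- ccg$count > band$upper
  sig_bins <- ccg$lag_ms[in_int & exceed]
  list(significant = length(sig_bins) > 0,
       significant_bins = sig_bins,
       peak_within_25ms = any(abs(centers[in_int & exceed]) <= 25))
}

# flatten a raster into (latencies s, event index), sorted by (event, lat)
raster_flat <- function(raster) {
  ev <- rep.int(seq_along(raster$latencies), lengths(raster$latencies))
  lat <- unlist(raster$latencies) / 1000
  if (!length(lat)) return(list(lat = numeric(0), ev = integer(0)))
  ord <- order(ev, lat)
  list(lat = lat[ord], ev = as.integer(ev[ord]))
}

#' Peri-event coincidence counts for a unit pair
#'
#' A coincidence is an ordered cross pair (one spike of each unit, same
#' event) with `|t_b - t_a| <= window_ms / 2`; it is assigned to the
#' peri-event bin of the earlier spike. This makes the count a pure pair
#' count with an exhaustive oracle.
#'
#' @param raster_a,raster_b [peri_event_raster] objects for the two units
#'   over the same events (equal `n_events`).
#' @param window_ms total coincidence window (default 5 ms).
#' @param bin_ms peri-event bin width (default 10 ms).
#' @param rule `"pairs"` counts every qualifying cross pair (the default;
#'   admits an exhaustive oracle); `"greedy"` matches each spike to at
#'   most one coincidence partner.
#' @return A `coincidence_series`: data frame `t_ms` (bin left edge),
#'   `count`, with window/bin attributes.
#' @export
coincidence_series <- function(raster_a, raster_b, window_ms = 5, bin_ms = 10,
                               rule = c("pairs", "greedy")) {
  rule <- match.arg(rule)
  stopifnot(raster_a$n_events == raster_b$n_events,
            raster_a$halfwidth_ms == raster_b$halfwidth_ms)
  hw <- raster_a$halfwidth_ms / 1000
  fa <- raster_flat(raster_a); fb <- raster_flat(raster_b)
  counts <- .coincidence_count_cpp(fa$lat, fa$ev, fb$lat, fb$ev,
                                   window_ms / 2000, bin_ms / 1000, -hw, hw,
                                   match(rule, c("pairs", "greedy")) - 1L)
  nb <- length(counts)
  df <- data.frame(t_ms = -raster_a$halfwidth_ms + bin_ms * (seq_len(nb) - 1L),
                   count = counts)
  structure(df, class = c("coincidence_series", "data.frame"),
            window_ms = window_ms, bin_ms = bin_ms, rule = rule,
            n_events = raster_a$n_events,
            halfwidth_ms = raster_a$halfwidth_ms)
}

#' Dither-surrogate per-bin coincidence thresholds
#'
#' Each surrogate independently displaces every spike latency of both
#' units by a uniform offset on `[-halfwidth_ms, +halfwidth_ms]` (clipped
#' to the raster window minus a tiny epsilon, preserving counts), then
#' recounts coincidences; the per-bin threshold is the empirical
#' `1 - p` quantile of the surrogate counts.
#'
#' @inheritParams coincidence_series
#' @param halfwidth_ms dither half-width in ms (default 5).
#' @param rule coincidence rule, as [coincidence_series].
#' @param n number of surrogates (default 1000).
#' @param p per-bin tail probability (default 0.001, i.e. a 99.9% level).
#' @param seed integer seed.
#' @return A data frame `t_ms`, `threshold` with attributes `n_surrogates`,
#'   `p`, `seed`.
#' @export
dither_threshold <- function(raster_a, raster_b, halfwidth_ms = 5, n = 1000,
                             p = 0.001, seed = 1L, window_ms = 5, bin_ms = 10,
                             rule = c("pairs", "greedy")) {
  rule <- match.arg(rule)
  stopifnot(raster_a$n_events == raster_b$n_events,
            raster_a$halfwidth_ms == raster_b$halfwidth_ms)
  hw <- raster_a$halfwidth_ms / 1000
  fa <- raster_flat(raster_a); fb <- raster_flat(raster_b)
  surr <- with_seed(seed,
    .coincidence_dither_surr_cpp(fa$lat, fa$ev, fb$lat, fb$ev,
                                 window_ms / 2000, bin_ms / 1000, -hw, hw,
                                 halfwidth_ms / 1000, n,
                                 match(rule, c("pairs", "greedy")) - 1L))
  thr <- apply(surr, 1, stats::quantile, probs = 1 - p, names = FALSE)
  nb <- nrow(surr)
  structure(data.frame(t_ms = -raster_a$halfwidth_ms + bin_ms * (seq_len(nb) - 1L),
                       threshold = thr),
            n_surrogates = n, p = p, seed = seed,
            class = c("dither_threshold", "data.frame"))
}

#' Significant coincidence bins
#'
#' Bins whose observed coincidence count strictly exceeds the surrogate
#' threshold; the overall flag is true when any such bin lies in the
#' pre-ID or ID window.
#'
#' @param series a [coincidence_series].
#' @param thresholds a [dither_threshold] for the same pair.
#' @param windows a [peri_event_windows] list (defines pre-ID/ID).
#' @return A list `significant_bins` (t_ms), `significant` (any exceeding
#'   bin in pre-ID or ID).
#' @export
coincidence_significant <- function(series, thresholds,
                                    windows = peri_event_windows()) {
  stopifnot(nrow(series) == nrow(thresholds))
  exceed <- series$count > thresholds$threshold
  centers <- series$t_ms + attr(series, "bin_ms") / 2
  in_focus <- in_window(centers, windows$pre_id) | in_window(centers, windows$id)
  list(significant_bins = series$t_ms[exceed],
       significant = any(exceed & in_focus))
}

#' Run both synchrony tests for one unit pair
#'
#' @param a,b [spike_train] objects.
#' @param events an [event_set].
#' @param seed master seed; the pair stream is derived from it and the two
#'   unit ids, so results do not depend on analysis order.
#' @param n_surrogates surrogates for both tests.
#' @param ccg_sd_ms,coin_halfwidth_ms surrogate parameters.
#' @param windows a [peri_event_windows] list.
#' @param min_spikes pair eligibility threshold.
#' @return A one-row data frame with both tests' flags and peak info, or
#'   NULL (with a message) for ineligible pairs.
#' @export
analyze_pair <- function(a, b, events, seed = 1L, n_surrogates = 1000,
                         ccg_sd_ms = 50, coin_halfwidth_ms = 5,
                         windows = peri_event_windows(), min_spikes = 100) {
  if (length(a$times) <= min_spikes || length(b$times) <= min_spikes) {
    message(sprintf("pair %s/%s skipped: needs > %d spikes each",
                    a$unit_id, b$unit_id, min_spikes))
    return(NULL)
  }
  pair_seed <- derive_seed(seed, paste("pair", a$unit_id, b$unit_id))
  ccg <- cross_correlogram(a, b, min_spikes = min_spikes)
  band <- jitter_band(a, b, sd_ms = ccg_sd_ms, n = n_surrogates,
                      seed = pair_seed, min_spikes = min_spikes)
  cs <- ccg_significant(ccg, band)
  ra <- peri_event_raster(a, events)
  rb <- peri_event_raster(b, events)
  series <- coincidence_series(ra, rb)
  thr <- dither_threshold(ra, rb, halfwidth_ms = coin_halfwidth_ms,
                          n = n_surrogates,
                          seed = derive_seed(pair_seed, "dither"))
  co <- coincidence_significant(series, thr, windows)
  data.frame(unit_a = a$unit_id, unit_b = b$unit_id,
             ccg_significant = cs$significant,
             ccg_peak_within_25ms = cs$peak_within_25ms,
             ccg_n_sig_bins = length(cs$significant_bins),
             ccg_peak_lag_ms = ccg$lag_ms[which.max(ccg$count)],
             coincidence_significant = co$significant,
             coincidence_n_sig_bins = length(co$significant_bins),
             stringsAsFactors = FALSE)
}
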