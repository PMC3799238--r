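test_that("cross-correlogram matches the exhaustive O(n^2) oracle", {
  for (s in 1:5) {
    a <- poisson_train(4, span = c(0, 150), unit_id = "a", seed = 400 + s)
    b <- poisson_train(3, span = c(0, 150), unit_id = "b", seed = 500 + s)
    ccg <- cross_correlogram(a, b)
    expect_equal(as.integer(ccg$count), as.integer(ccg_oracle(a, b)))
  }
})

test_that("correlogram peaks at zero for identical trains and shifts with a lag", {
  a <- poisson_train(5, span = c(0, 200), unit_id = "a", seed = 42)
  self <- cross_correlogram(a, a)
  expect_equal(self$lag_ms[which.max(self$count)], 0)

  b <- spike_train(a$times + 0.0105, span = c(0, 201), unit_id = "b")
  sh <- cross_correlogram(a, b)
  expect_equal(sh$lag_ms[which.max(sh$count)], 10)
})

test_that("pairs without enough spikes are rejected", {
  a <- poisson_train(5, span = c(0, 100), seed = 1)
  tiny <- spike_train(seq(1, 50, by = 1), span = c(0, 100), unit_id = "t")
  expect_error(cross_correlogram(a, tiny), "> 100 spikes")
})

test_that("zero-SD jitter collapses the band onto the observed correlogram", {
  a <- poisson_train(4, span = c(0, 150), unit_id = "a", seed = 61)
  b <- poisson_train(4, span = c(0, 150), unit_id = "b", seed = 62)
  ccg <- cross_correlogram(a, b)
  band <- jitter_band(a, b, sd_ms = 0, n = 50, seed = 3)
  expect_equal(band$lower, as.numeric(ccg$count))
  expect_equal(band$upper, as.numeric(ccg$count))
})

test_that("surrogate bands are bit-reproducible under a fixed seed", {
  a <- poisson_train(4, span = c(0, 150), unit_id = "a", seed = 71)
  b <- poisson_train(4, span = c(0, 150), unit_id = "b", seed = 72)
  b1 <- jitter_band(a, b, n = 200, seed = 99)
  b2 <- jitter_band(a, b, n = 200, seed = 99)
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)

  ev <- regular_events(3, 147, by = 3)
  ra <- peri_event_raster(a, ev); rb <- peri_event_raster(b, ev)
  t1 <- dither_threshold(ra, rb, n = 200, seed = 77)
  t2 <- dither_threshold(ra, rb, n = 200, seed = 77)
  expect_identical(t1$threshold, t2$threshold)
})

test_that("jitter surrogates preserve counts and slow rate structure", {
  # strongly rate-modulated train around events
  cfg <- sim_config(duration_s = 500, event_rate_hz = 0.2,
                    units = sim_units_spec(n = 2,
                                           classes = c("id_increase", "id_increase"),
                                           baseline_hz = 6,
                                           gains = c(id_increase = 5)),
                    master_seed = 15)
  gl <- gen_lfp(cfg); gu <- gen_units(cfg, gl$truth_events)
  a <- gu$trains[[1]]; b <- gu$trains[[2]]

  # the surrogate operation: every spike gets an independent N(0, 50 ms) offset
  aj <- spike_train(sort(a$times + iedflow:::with_seed(3, rnorm(length(a$times), 0, 0.05))),
                    span = a$span + c(-1, 1), unit_id = "aj")
  expect_length(aj$times, length(a$times))        # counts preserved exactly
  # rate profiles at timescales >> jitter SD are preserved
  grid <- seq(1, 499, by = 0.05)
  prof <- function(tr) {
    rt <- instantaneous_rate(spike_train(tr$times, span = c(0, 500)), sigma_ms = 200)
    rt$values[round((grid - rt$t_start) / rt$dt) + 1]
  }
  expect_gt(stats::cor(prof(a), prof(aj)), 0.95)

  # total pair count is preserved on average (jitter only moves spikes locally)
  ccg <- cross_correlogram(a, b)
  band <- jitter_band(a, b, n = 400, seed = 8)
  expect_equal(sum(attr(band, "mean_count")), sum(ccg$count), tolerance = 0.1)
})

test_that("ccg significance applies the decision interval and the 25-ms flag", {
  nb <- 200
  ccg <- structure(data.frame(lag_ms = -100:99, count = rep(5L, nb)),
                   class = c("cross_correlogram", "data.frame"),
                   bin_ms = 1, max_lag_ms = 100)
  band <- data.frame(lag_ms = -100:99, lower = rep(0, nb), upper = rep(10, nb))
  expect_false(ccg_significant(ccg, band)$significant)

  ccg$count[ccg$lag_ms == 4] <- 12L
  s <- ccg_significant(ccg, band)
  expect_true(s$significant)
  expect_equal(s$significant_bins, 4)
  expect_true(s$peak_within_25ms)

  # exceedance outside [1.5, 30] ms does not count
  ccg$count[ccg$lag_ms == 4] <- 5L
  ccg$count[ccg$lag_ms == 60] <- 12L
  expect_false(ccg_significant(ccg, band)$significant)
})

test_that("an injected correlated pair is declared significant", {
  hits <- 0
  for (s in 1:5) {
    p <- gen_correlated_pair(5, 0.15, 3, span = c(0, 300), seed = 900 + s)
    ccg <- cross_correlogram(p$a, p$b)
    band <- jitter_band(p$a, p$b, n = 1000, seed = 900 + s)
    res <- ccg_significant(ccg, band)
    hits <- hits + res$significant
  }
  expect_gte(hits, 4)   # power >= 0.9 at fraction 0.15, 3-ms jitter
})

test_that("coincidence counting matches the brute-force oracle and its edge rules", {
  ev <- regular_events(3, 117, by = 3)
  a <- poisson_train(6, span = c(0, 120), unit_id = "a", seed = 81)
  b <- poisson_train(6, span = c(0, 120), unit_id = "b", seed = 82)
  ra <- peri_event_raster(a, ev); rb <- peri_event_raster(b, ev)
  cs <- coincidence_series(ra, rb)
  expect_equal(as.integer(cs$count), as.integer(coincidence_oracle(ra, rb)))

  # disjoint firing: A before the peak, B after -> no coincidences
  mk_raster <- function(lat, n_ev) structure(
    list(unit_id = "x", latencies = rep(list(lat), n_ev), n_events = n_ev,
         halfwidth_ms = 1000, n_dropped = 0L), class = "peri_event_raster")
  csd <- coincidence_series(mk_raster(c(-500, -200), 10), mk_raster(c(200, 500), 10))
  expect_true(all(csd$count == 0))

  # A at -100 ms, B at -98 ms -> one coincidence in the -100 ms bin
  cs1 <- coincidence_series(mk_raster(-100, 1), mk_raster(-98, 1))
  expect_equal(sum(cs1$count), 1)
  expect_equal(cs1$t_ms[cs1$count == 1], -100)

  # greedy rule: each spike pairs at most once (2x2 cluster -> 4 vs 2)
  csp <- coincidence_series(mk_raster(c(-100, -99), 1), mk_raster(c(-100, -99), 1))
  csg <- coincidence_series(mk_raster(c(-100, -99), 1), mk_raster(c(-100, -99), 1),
                            rule = "greedy")
  expect_equal(sum(csp$count), 4)
  expect_equal(sum(csg$count), 2)
})

test_that("dither thresholds are bounded order statistics and degenerate at width 0", {
  ev <- regular_events(3, 117, by = 3)
  a <- poisson_train(6, span = c(0, 120), unit_id = "a", seed = 83)
  b <- poisson_train(6, span = c(0, 120), unit_id = "b", seed = 84)
  ra <- peri_event_raster(a, ev); rb <- peri_event_raster(b, ev)
  thr <- dither_threshold(ra, rb, n = 300, seed = 5)
  # interpolated quantiles of integer counts: non-negative, at most the
  # largest surrogate count (which cannot exceed the total pair count)
  expect_true(all(thr$threshold >= 0))
  expect_true(all(thr$threshold <= length(unlist(ra$latencies)) *
                    length(unlist(rb$latencies))))

  cs <- coincidence_series(ra, rb)
  thr0 <- dither_threshold(ra, rb, halfwidth_ms = 0, n = 20, seed = 5)
  expect_equal(as.numeric(thr0$threshold), as.numeric(cs$count))
})

test_that("coincidence significance flags injected co-firing in the ID window", {
  ev <- regular_events(5, 295, by = 2)
  n_ev <- nrow(ev)
  base_a <- poisson_train(5, span = c(0, 300), unit_id = "a", seed = 85)
  base_b <- poisson_train(5, span = c(0, 300), unit_id = "b", seed = 86)
  # inject near-simultaneous spikes during the ID window of every event
  inj <- ev$peak_time + 0.01
  a <- spike_train(sort(c(base_a$times, inj)), span = c(0, 300), unit_id = "a")
  b <- spike_train(sort(c(base_b$times, inj + 0.001)), span = c(0, 300), unit_id = "b")
  ra <- peri_event_raster(a, ev); rb <- peri_event_raster(b, ev)
  cs <- coincidence_series(ra, rb)
  thr <- dither_threshold(ra, rb, n = 500, seed = 9)
  res <- coincidence_significant(cs, thr)
  expect_true(res$significant)
  expect_true(any(res$significant_bins >= -50 & res$significant_bins < 50))

  # independent pair: not significant
  ra0 <- peri_event_raster(base_a, ev); rb0 <- peri_event_raster(base_b, ev)
  res0 <- coincidence_significant(coincidence_series(ra0, rb0),
                                  dither_threshold(ra0, rb0, n = 500, seed = 10))
  expect_false(res0$significant)
})

test_that("analyze_pair assembles both tests deterministically", {
  ev <- regular_events(5, 295, by = 2)
  p <- gen_correlated_pair(5, 0.2, 2, span = c(0, 300), seed = 17)
  r1 <- analyze_pair(p$a, p$b, ev, seed = 3, n_surrogates = 200)
  r2 <- analyze_pair(p$a, p$b, ev, seed = 3, n_surrogates = 200)
  expect_identical(r1, r2)
  expect_true(r1$ccg_significant)
  tiny <- spike_train(1:50, span = c(0, 300), unit_id = "t")
  expect_message(res <- analyze_pair(p$a, tiny, ev, seed = 3, n_surrogates = 50),
                 "skipped")
  expect_null(res)
})
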