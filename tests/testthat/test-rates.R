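test_that("ISI violation fraction counts refractory intervals", {
  expect_equal(isi_violation_fraction(spike_train(1, span = c(0, 2))), 0)
  tr <- spike_train(c(0, 0.0005, 1, 2), span = c(0, 3))
  expect_equal(isi_violation_fraction(tr), 1 / 3)
  expect_false(passes_isi_filter(tr))
  clean <- spike_train(seq(0, 10, by = 0.05), span = c(0, 11))
  expect_true(passes_isi_filter(clean))
})

test_that("instantaneous rate integrates to the spike count and peaks at the closed form", {
  empty <- instantaneous_rate(spike_train(numeric(), span = c(0, 5)))
  expect_true(all(empty$values == 0))

  one <- instantaneous_rate(spike_train(2.5, span = c(0, 5)))
  expect_equal(max(one$values), 1 / (0.020 * sqrt(2 * pi)), tolerance = 1e-3)
  expect_equal(one$values[which.max(one$values)],
               one$values[round((2.5 - one$t_start) / one$dt) + 1])

  for (s in 1:5) {
    tr <- poisson_train(8, span = c(0, 20), seed = 100 + s)
    rt <- instantaneous_rate(tr)
    expect_equal(sum(rt$values) * rt$dt, length(tr$times), tolerance = 1e-6)
  }
})

test_that("peri-event raster matches a brute-force double loop and boundary rules", {
  tr <- poisson_train(6, span = c(0, 120), seed = 21)
  ev <- regular_events(3, 117, by = 3)
  r <- peri_event_raster(tr, ev)
  expect_equal(r$n_events, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    pk <- ev$peak_time[i]
    want <- (tr$times[tr$times >= pk - 1 & tr$times < pk + 1] - pk) * 1000
    expect_equal(r$latencies[[i]], want)
  }

  # spike exactly at the peak -> latency 0 included (half-open window)
  tr0 <- spike_train(c(1, 5), span = c(0, 10))
  r0 <- peri_event_raster(tr0, event_set(peak_time = 5))
  expect_equal(r0$latencies[[1]], 0)

  # events without the 1-s margin are dropped and counted
  rdrop <- peri_event_raster(tr0, event_set(peak_time = c(0.5, 5)))
  expect_equal(rdrop$n_events, 1)
  expect_equal(rdrop$n_dropped, 1)
})

test_that("PSTH conserves counts and is flat for a homogeneous unit", {
  tr <- poisson_train(5, span = c(0, 500), seed = 31)
  ev <- regular_events(3, 497, by = 2.5)   # ~198 events
  r <- peri_event_raster(tr, ev)
  h <- psth(r, bin_ms = 10)
  expect_equal(nrow(h), 200)
  expect_equal(sum(h$count), sum(lengths(r$latencies)))
  se <- sqrt(5 / (r$n_events * 0.010))
  expect_true(all(abs(h$rate_hz - 5) < 4 * se))

  h0 <- psth(structure(list(unit_id = "x", latencies = list(), n_events = 0L,
                            halfwidth_ms = 1000, n_dropped = 0L),
                       class = "peri_event_raster"))
  expect_true(all(h0$rate_hz == 0))
  expect_error(psth(r, bin_ms = 7), "evenly")
})

test_that("modulation classes recover generator ground truth per class", {
  cfg <- sim_config(duration_s = 900, event_rate_hz = 0.2,
                    units = sim_units_spec(
                      n = 3, classes = c("none", "id_increase", "post_decrease"),
                      baseline_hz = c(4, 3, 5),
                      gains = c(none = 1, id_increase = 3, post_decrease = 0.4)),
                    master_seed = 8)
  gl <- gen_lfp(cfg)
  gu <- gen_units(cfg, gl$truth_events)
  expect_gte(nrow(gl$truth_events), 100)
  mods <- lapply(gu$trains, function(tr)
    classify_modulation(peri_event_raster(tr, gl$truth_events)))
  expect_equal(mods$u01$class_id, "none")
  expect_equal(mods$u02$class_id, "increase")
  expect_gt(mods$u02$ratio_id, 2)
  expect_equal(mods$u03$class_post, "decrease")
  expect_lt(mods$u03$ratio_post, 0.5)
})

test_that("a constant-rate unit is rarely classified as pre-ID modulated", {
  hits <- 0
  for (s in 1:10) {
    tr <- poisson_train(5, span = c(0, 500), seed = 300 + s)
    ev <- regular_events(3, 497, by = 2.5)
    m <- classify_modulation(peri_event_raster(tr, ev))
    hits <- hits + (m$class_pre != "none") + (m$class_id != "none")
  }
  expect_lte(hits, 2)   # ~5% nominal level per unit and test
})

test_that("silent baseline uses the rate floor and flags the result", {
  lat <- lapply(1:20, function(i) c(-10, 10))  # spikes only in the ID window
  r <- structure(list(unit_id = "sil", latencies = lat, n_events = 20L,
                      halfwidth_ms = 1000, n_dropped = 0L),
                 class = "peri_event_raster")
  m <- classify_modulation(r)
  expect_true(m$baseline_floored)
  expect_equal(m$ratio_id, (20 + 0.1) / 0.1, tolerance = 1e-9)
  expect_equal(m$class_id, "increase")
})

test_that("group rate test matches the closed-form t distribution", {
  g <- group_rate_test(c(1, 2, 3), c(0, 0, 0), tail = "right")
  expect_equal(g$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(g$df, 2)
  expect_equal(g$p, stats::pt(2 * sqrt(3), 2, lower.tail = FALSE))
  expect_equal(g$p, 0.0371, tolerance = 2e-3)

  z <- group_rate_test(c(1, 1, 1), c(1, 1, 1), tail = "right")
  expect_equal(z$t, 0)
  expect_equal(z$p, 0.5)
  expect_true(z$degenerate)

  # df is n - 1, as in across-unit paired group comparisons
  g24 <- group_rate_test(rnorm(24, 1), rnorm(24), tail = "right")
  expect_equal(g24$df, 23)
})

test_that("classification is invariant to event relabeling and time translation", {
  cfg <- sim_config(duration_s = 400, event_rate_hz = 0.15,
                    units = sim_units_spec(n = 1, classes = "id_increase",
                                           baseline_hz = 4),
                    master_seed = 77)
  gl <- gen_lfp(cfg); gu <- gen_units(cfg, gl$truth_events)
  tr <- gu$trains[[1]]
  ev <- gl$truth_events
  m1 <- classify_modulation(peri_event_raster(tr, ev))

  # shift the whole dataset by 13.7 s
  sh <- 13.7
  tr2 <- spike_train(tr$times + sh, span = tr$span + sh, unit_id = tr$unit_id)
  ev2 <- event_set(peak_time = ev$peak_time + sh, onset = ev$onset + sh,
                   offset = ev$offset + sh, peak_amplitude = ev$peak_amplitude)
  m2 <- classify_modulation(peri_event_raster(tr2, ev2))
  for (cl in c("rate_baseline", "rate_id", "ratio_id", "class_id", "p_pre"))
    expect_equal(m2[[cl]], m1[[cl]], tolerance = 1e-9)
})
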