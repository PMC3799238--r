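test_that("LFP generator honours rate, refractory and amplitude targets", {
  cfg0 <- sim_config(duration_s = 60, event_rate_hz = 0, master_seed = 1)
  g0 <- gen_lfp(cfg0)
  expect_equal(nrow(g0$truth_events), 0)
  expect_length(g0$lfp$samples, 60000)

  cfg <- sim_config(duration_s = 600, master_seed = 2)
  g <- gen_lfp(cfg)
  lam <- 0.07 * 600
  expect_lt(abs(nrow(g$truth_events) - lam), 3 * sqrt(lam))
  expect_true(all(diff(g$truth_events$peak_time) >= 2))

  # template peak amplitude over background robust SD ~ id_amp_snr
  bg <- stats::mad(g0$lfp$samples)
  pk_dev <- abs(g$lfp$samples[round(g$truth_events$peak_time * 1000) + 1])
  expect_lt(abs(median(pk_dev) / bg - cfg$id_amp_snr) / cfg$id_amp_snr, 0.10)

  expect_error(gen_lfp(sim_config(event_rate_hz = 0.6)), "refractory")
})

test_that("unit generator matches its analytic rate targets within 3 SE", {
  cfg <- sim_config(duration_s = 800, event_rate_hz = 0.15,
                    units = sim_units_spec(
                      n = 2, classes = c("none", "id_increase"),
                      baseline_hz = 3,
                      gains = c(none = 1, id_increase = 3)),
                    master_seed = 3)
  gl <- gen_lfp(cfg)
  gu <- gen_units(cfg, gl$truth_events)
  n_ev <- nrow(gl$truth_events)
  expect_gte(n_ev, 80)

  # class none: homogeneous
  n1 <- length(gu$trains$u01$times)
  expect_lt(abs(n1 - 3 * 800), 3 * sqrt(3 * 800))

  # id_increase: ID-window rate ~ baseline x gain
  r <- peri_event_raster(gu$trains$u02, gl$truth_events)
  idc <- sum(vapply(r$latencies, function(l) sum(l >= -50 & l < 50), 0L))
  expeced <- 9 * 0.1 * r$n_events
  expect_lt(abs(idc - expeced), 3 * sqrt(expeced))

  # refractory enforced: passes the ISI quality filter by construction
  for (tr in gu$trains) {
    if (length(tr$times) > 1) expect_gte(min(diff(tr$times)), 0.0015)
    expect_true(passes_isi_filter(tr))
  }
})

test_that("correlated-pair generator spans the independence-to-identity range", {
  p0 <- gen_correlated_pair(5, 0, 3, span = c(0, 200), seed = 5)
  expect_false(isTRUE(all.equal(p0$a$times, p0$b$times)))

  p1 <- gen_correlated_pair(5, 1, 0, span = c(0, 200), seed = 6)
  expect_identical(p1$a$times, p1$b$times)

  # fraction 0.15, 3-ms jitter: central correlogram mass within |lag| <= 10 ms
  p <- gen_correlated_pair(8, 0.15, 3, span = c(0, 400), seed = 7)
  ccg <- cross_correlogram(p$a, p$b)
  base <- mean(ccg$count[abs(ccg$lag_ms) > 30])
  excess <- ccg$count - base
  core <- abs(ccg$lag_ms + 0.5) <= 10
  expect_gt(sum(excess[core]), 0.8 * sum(excess[abs(ccg$lag_ms + 0.5) <= 50]))
})

test_that("datasets regenerate byte-identically and the config echo round-trips", {
  cfg <- sim_config(duration_s = 90, event_rate_hz = 0.1,
                    units = sim_units_spec(n = 3), master_seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_dataset(cfg, d1, force = TRUE)
  gen_dataset(cfg, d2, force = TRUE)
  for (f in c("lfp.csv", "spikes.csv", "events_truth.csv", "classes_truth.csv",
              "config.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_error(gen_dataset(cfg, d1), "force")

  cfg2 <- read_sim_config(file.path(d1, "config.json"))
  expect_equal(cfg2$event_rate_hz, cfg$event_rate_hz)
  expect_equal(cfg2$units$class, cfg$units$class)
  expect_equal(cfg2$master_seed, cfg$master_seed)

  # generated artifacts pass the package's own readers
  trains <- read_spike_trains(file.path(d1, "spikes.csv"))
  expect_length(trains, 3)
  ev <- read_events(file.path(d1, "events_truth.csv"))
  expect_s3_class(ev, "event_set")
  lfp <- read_lfp(file.path(d1, "lfp.csv"))
  expect_equal(lfp$fs, 1000)
})

test_that("substreams decouple: unit regeneration does not disturb the LFP", {
  cfg <- sim_config(duration_s = 60, event_rate_hz = 0.1, master_seed = 21,
                    units = sim_units_spec(n = 2))
  a <- gen_lfp(cfg)
  invisible(gen_units(cfg, a$truth_events))
  b <- gen_lfp(cfg)
  expect_identical(a$lfp$samples, b$lfp$samples)
  expect_identical(a$truth_events$peak_time, b$truth_events$peak_time)
  expect_true(derive_seed(1, "lfp") != derive_seed(1, "units"))
  expect_true(derive_seed(1, "lfp") != derive_seed(2, "lfp"))
})
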