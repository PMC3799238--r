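test_that("Morlet power vanishes on a zero signal and is 2-homogeneous", {
  lfp <- lfp_signal(rep(0, 4000), 1000)
  tf <- morlet_transform(lfp, morlet_params(freqs = seq(20, 200, by = 20)))
  expect_true(all(tf$values == 0))

  x <- iedflow:::with_seed(4, rnorm(4000))
  p1 <- morlet_transform(lfp_signal(x, 1000), morlet_params(freqs = c(40, 80)))
  p2 <- morlet_transform(lfp_signal(2 * x, 1000), morlet_params(freqs = c(40, 80)))
  expect_equal(p2$values, 4 * p1$values, tolerance = 1e-10)
})

test_that("a pure tone peaks at its own frequency within half a step", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  for (f0 in c(44, 80, 160)) {
    tf <- morlet_transform(lfp_signal(sin(2 * pi * f0 * t), fs))
    prof <- colSums(tf$values * tf$valid) / colSums(tf$valid)
    expect_equal(tf$freqs[which.max(prof)], f0)
  }
})

test_that("tone response width follows the analytic Gaussian of sigma(f) = nco/(6f)", {
  fs <- 1000; f0 <- 100; nco <- 5
  t <- seq(0, 6, by = 1 / fs)
  tf <- morlet_transform(lfp_signal(sin(2 * pi * f0 * t), fs),
                         morlet_params(freqs = seq(60, 140, by = 2), nco = nco))
  prof <- colSums(tf$values * tf$valid) / colSums(tf$valid)
  prof <- prof / max(prof)
  # analytic amplitude response: exp(-2 pi^2 sigma(f)^2 (f - f0)^2), power = square
  sig <- nco / (6 * tf$freqs)
  ana <- exp(-4 * pi^2 * sig^2 * (tf$freqs - f0)^2)
  core <- ana > 0.05
  expect_lt(max(abs(prof[core] - ana[core])), 0.05)
})

test_that("frequencies at or above Nyquist and too-short traces are rejected", {
  expect_error(morlet_transform(lfp_signal(rnorm(4000), 1000),
                                morlet_params(freqs = c(100, 600))), "Nyquist")
  expect_error(morlet_transform(lfp_signal(rnorm(300), 1000),
                                morlet_params(freqs = 20)), "10 cycles")
})

test_that("baseline Z-scoring self-normalises and is scale-invariant", {
  cfg <- sim_config(duration_s = 120, event_rate_hz = 0, master_seed = 9)
  noise <- gen_lfp(cfg)$lfp
  ev <- event_set(peak_time = seq(5, 115, by = 5))
  par <- morlet_params(freqs = seq(20, 120, by = 10))
  tz <- event_tf_zscore(noise, ev, par)
  bl <- tz$times >= -0.6 & tz$times < -0.3
  expect_lt(abs(mean(tz$values[bl, ][tz$valid[bl, ]])), 0.05)

  scaled <- lfp_signal(noise$samples * 7.3, noise$fs)
  tz2 <- event_tf_zscore(scaled, ev, par)
  expect_equal(tz2$values, tz$values, tolerance = 1e-8)
})

test_that("an injected pre-ID gamma burst exceeds the Z > 3.09 cutoff at its frequency", {
  cfg <- sim_config(duration_s = 250, master_seed = 10,
                    preid_burst = list(on = TRUE, freq_hz = 90,
                                       window_ms = c(-300, -50), gain = 10))
  gl <- gen_lfp(cfg)
  tz <- event_tf_zscore(prepare_lfp(gl$lfp), gl$truth_events)
  sc <- preid_hfo_score(tz)
  expect_gt(sc$peak_z, 3.09)
  expect_lt(abs(sc$peak_freq_hz - 90), 10)
  expect_true(sc$peak_time_ms >= -300 && sc$peak_time_ms < -50)

  # without a burst the pre-ID band stays below the cutoff
  cfg0 <- sim_config(duration_s = 250, master_seed = 10)
  gl0 <- gen_lfp(cfg0)
  tz0 <- event_tf_zscore(prepare_lfp(gl0$lfp), gl0$truth_events)
  expect_lt(preid_hfo_score(tz0)$peak_z, 3.09)
})

test_that("significance mask keeps only valid cells beyond the cutoff", {
  z <- matrix(0, 10, 4)
  tf <- structure(list(times = seq(0, 0.9, by = 0.1), freqs = c(20, 40, 60, 80),
                       values = z, valid = matrix(TRUE, 10, 4), mode = "zscore",
                       fs = 1000), class = "tf_map")
  expect_equal(sum(significant_tf_mask(tf)), 0)
  tf$values[3, 2] <- 3.10
  expect_equal(sum(significant_tf_mask(tf)), 1)
  tf$values[5, 3] <- -4
  expect_equal(sum(significant_tf_mask(tf)), 2)
  expect_equal(sum(significant_tf_mask(tf, tail = "one")), 1)
  tf$valid[3, 2] <- FALSE
  expect_equal(sum(significant_tf_mask(tf, tail = "one")), 0)

  # on standard normal scores the masked fraction matches the normal tail
  tfn <- tf
  tfn$values <- matrix(iedflow:::with_seed(6, rnorm(4e5)), 1e5, 4)
  tfn$valid <- matrix(TRUE, 1e5, 4)
  frac <- mean(significant_tf_mask(tfn))
  p <- 2 * stats::pnorm(3.09, lower.tail = FALSE)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 4e5))
})

test_that("Lilliefors normality check holds its level and rejects uniforms", {
  rej <- 0
  for (s in 1:60) {
    r <- ks_normality(iedflow:::with_seed(700 + s, rnorm(2000)))
    expect_true(r$D >= 0 && r$D <= 1)
    rej <- rej + r$reject
  }
  # ~5% nominal level; 3 binomial SE over 60 replicates
  expect_lt(abs(rej / 60 - 0.05), 3 * sqrt(0.05 * 0.95 / 60))

  u <- ks_normality(iedflow:::with_seed(13, runif(1e4)))
  expect_true(u$reject)
  expect_error(ks_normality(rep(1, 100)), "constant")
  expect_error(ks_normality(rnorm(5)), ">= 10")
})
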