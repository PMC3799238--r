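# Morlet wavelet time-frequency analysis with baseline Z-normalisation.
#
# Wavelet: Psi_{tau,f}(u) = f * exp(j 2 pi f (u - tau)) * exp(-(u - tau)^2 / (2 sigma^2)),
# with sigma set by the number-of-cycles parameter, nco = 6 f sigma (default
# nco = 5). With the prefactor f the tone response f * sigma(f) * sqrt(2 pi)
# is flat in frequency, so a pure tone's power peaks exactly at the tone
# frequency. Power is |W|^2. Samples within half the kernel support of
# either trace edge are marked invalid and never enter baselines, masks or
# scores.

#' Morlet analysis parameters
#'
#' @param freqs analysed frequencies in Hz (default 20-300 Hz in 2-Hz steps).
#' @param nco number-of-cycles parameter; `sigma(f) = nco / (6 f)`.
#' @return A `morlet_params` list.
#' @export
morlet_params <- function(freqs = seq(20, 300, by = 2), nco = 5) {
  stopifnot(nco > 0, all(freqs > 0))
  structure(list(freqs = as.numeric(freqs), nco = nco), class = "morlet_params")
}

# complex "same" convolution by FFT, kernel centred
conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  half <- (m - 1L) %/% 2L
  N <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, rep(0, N - n)))
  K <- stats::fft(c(k, rep(0, N - m)))
  full <- stats::fft(X * K, inverse = TRUE) / N
  full[(half + 1L):(half + n)]
}

#' Morlet wavelet transform (power)
#'
#' Convolves the trace with complex Morlet wavelets (kernel truncated at
#' +/- 5 sigma) and returns power `|W|^2` as a time x frequency map.
#'
#' @param lfp an [lfp_signal]; must be at least 10 cycles of the lowest
#'   analysed frequency long, and all frequencies must be below Nyquist.
#' @param params a [morlet_params] list.
#' @return A `tf_map`: list with `times` (s), `freqs` (Hz), `values`
#'   (time x freq matrix), `valid` (logical matrix, FALSE within half a
#'   kernel of an edge), `mode = "power"`, `fs`.
#' @export
morlet_transform <- function(lfp, params = morlet_params()) {
  fs <- lfp$fs
  if (any(params$freqs >= fs / 2))
    stop_fmt("morlet_transform: frequencies must be below Nyquist (%g Hz)", fs / 2)
  n <- length(lfp$samples)
  if (n / fs < 10 / min(params$freqs))
    stop_fmt("morlet_transform: trace shorter than 10 cycles of %g Hz",
             min(params$freqs))
  dt <- 1 / fs
  nf <- length(params$freqs)
  vals <- matrix(0, n, nf)
  valid <- matrix(TRUE, n, nf)
  for (j in seq_len(nf)) {
    f <- params$freqs[j]
    sigma <- params$nco / (6 * f)
    half <- ceiling(5 * sigma * fs)
    u <- (-half:half) * dt
    psi <- f * exp(2i * pi * f * u) * exp(-u^2 / (2 * sigma^2)) * dt
    w <- conv_same(lfp$samples, psi)
    vals[, j] <- Mod(w)^2
    if (half > 0) {
      edge <- min(half, n)
      valid[seq_len(edge), j] <- FALSE
      valid[n - seq_len(edge) + 1L, j] <- FALSE
    }
  }
  structure(list(times = lfp_times(lfp), freqs = params$freqs, values = vals,
                 valid = valid, mode = "power", fs = fs,
                 baseline_window_ms = NULL),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %s: %d times x %d freqs (%g-%g Hz), %.1f%% valid\n",
              x$mode, length(x$times), length(x$freqs), min(x$freqs),
              max(x$freqs), 100 * mean(x$valid)))
  invisible(x)
}

# row indices of a tf map whose times fall in [t0, t1)
tf_rows <- function(tf, t0, t1) which(tf$times >= t0 & tf$times < t1)

#' Baseline Z-scoring of peri-event power maps
#'
#' For each frequency, the mean and SD of power are pooled over all events'
#' baseline windows; the whole peri-event map is then converted to
#' `Z = (P - mean) / SD` and averaged across events after normalisation.
#' Positive Z marks power above baseline; `|Z| > 3.09` corresponds to
#' `P < 0.001` under a normal reference.
#'
#' @param tf a power-mode `tf_map` covering the events (absolute time base).
#' @param events an [event_set] (at least 2 events with valid baseline
#'   samples).
#' @param baseline_ms baseline window in ms relative to the event peak.
#' @param peri_ms peri-event window in ms retained in the output map.
#' @return A zscore-mode `tf_map` whose `times` are in seconds relative to
#'   the event peak; frequencies whose pooled baseline SD is zero are
#'   flagged invalid.
#' @export
baseline_zscore <- function(tf, events, baseline_ms = c(-600, -300),
                            peri_ms = c(-1000, 1000)) {
  if (tf$mode != "power") stop_fmt("baseline_zscore: need a power-mode tf_map")
  if (nrow(events) < 2) stop_fmt("baseline_zscore: need >= 2 events")
  per_event <- lapply(events$peak_time, function(pk) {
    rows <- tf_rows(tf, pk + peri_ms[1] / 1000, pk + peri_ms[2] / 1000)
    list(rows = rows, pk = pk)
  })
  n_per <- vapply(per_event, function(e) length(e$rows), 0L)
  nrow_out <- min(n_per)
  if (nrow_out < 2) stop_fmt("baseline_zscore: events outside the map")
  zscore_event_maps(
    power_list = lapply(per_event, function(e) {
      r <- e$rows[seq_len(nrow_out)]
      list(values = tf$values[r, , drop = FALSE],
           valid = tf$valid[r, , drop = FALSE],
           rel_times = tf$times[r] - e$pk)
    }),
    freqs = tf$freqs, fs = tf$fs, baseline_ms = baseline_ms)
}

# core: pool baselines across per-event power maps, z-score, average
zscore_event_maps <- function(power_list, freqs, fs, baseline_ms) {
  rel <- power_list[[1]]$rel_times
  nb <- length(freqs)
  base_rows_l <- lapply(power_list, function(e)
    which(e$rel_times >= baseline_ms[1] / 1000 & e$rel_times < baseline_ms[2] / 1000))
  mu <- sdv <- numeric(nb)
  for (j in seq_len(nb)) {
    pool <- unlist(lapply(seq_along(power_list), function(i) {
      e <- power_list[[i]]; r <- base_rows_l[[i]]
      e$values[r, j][e$valid[r, j]]
    }))
    if (length(pool) < 2) { mu[j] <- NA; sdv[j] <- 0; next }
    mu[j] <- mean(pool); sdv[j] <- stats::sd(pool)
  }
  ok_freq <- sdv > 0
  zsum <- matrix(0, length(rel), nb)
  vcnt <- matrix(0L, length(rel), nb)
  for (e in power_list) {
    z <- sweep(sweep(e$values, 2, mu), 2, ifelse(ok_freq, sdv, 1), "/")
    z[!e$valid] <- 0
    zsum <- zsum + z
    vcnt <- vcnt + e$valid
  }
  zavg <- ifelse(vcnt > 0, zsum / pmax(vcnt, 1L), NA_real_)
  valid <- vcnt == length(power_list)
  valid[, !ok_freq] <- FALSE
  structure(list(times = rel, freqs = freqs, values = zavg, valid = valid,
                 mode = "zscore", fs = fs,
                 baseline_window_ms = baseline_ms, n_events = length(power_list),
                 baseline_sd_ok = ok_freq),
            class = "tf_map")
}

#' Peri-event Morlet Z-map computed segment-wise
#'
#' Convenience wrapper for long recordings: extracts a padded segment
#' around each event peak, transforms each segment, and pools baselines
#' across events exactly as [baseline_zscore]. Memory use is independent of
#' recording length.
#'
#' @param lfp an [lfp_signal] (absolute time base shared with `events`).
#' @param events an [event_set].
#' @param params a [morlet_params] list.
#' @param baseline_ms,peri_ms windows in ms relative to the event peak.
#' @return A zscore-mode `tf_map` (times relative to the peak), as
#'   [baseline_zscore]. Events too close to the trace edges are dropped.
#' @export
event_tf_zscore <- function(lfp, events, params = morlet_params(),
                            baseline_ms = c(-600, -300),
                            peri_ms = c(-1000, 1000)) {
  fs <- lfp$fs
  pad <- 5 * params$nco / (6 * min(params$freqs)) + 2 / fs
  lo <- peri_ms[1] / 1000 - pad; hi <- peri_ms[2] / 1000 + pad
  tmin <- lfp$t0; tmax <- lfp$t0 + (length(lfp$samples) - 1) / fs
  pk_ok <- events$peak_time + lo >= tmin & events$peak_time + hi <= tmax
  if (sum(pk_ok) < 2) stop_fmt("event_tf_zscore: fewer than 2 usable events")
  # common relative sample grid
  i_lo <- ceiling(peri_ms[1] / 1000 * fs)
  i_hi <- floor(peri_ms[2] / 1000 * fs)
  power_list <- lapply(events$peak_time[pk_ok], function(pk) {
    seg <- lfp_crop(lfp, pk + lo, pk + hi)
    tfp <- morlet_transform(seg, params)
    ipk <- round((pk - seg$t0) * fs)            # 0-based peak sample in segment
    rows <- (ipk + i_lo):(ipk + i_hi) + 1L
    rows <- rows[rows >= 1 & rows <= length(seg$samples)]
    list(values = tfp$values[rows, , drop = FALSE],
         valid = tfp$valid[rows, , drop = FALSE],
         rel_times = (rows - 1L) / fs + seg$t0 - pk)
  })
  nr <- min(vapply(power_list, function(e) nrow(e$values), 0L))
  power_list <- lapply(power_list, function(e)
    list(values = e$values[seq_len(nr), , drop = FALSE],
         valid = e$valid[seq_len(nr), , drop = FALSE],
         rel_times = e$rel_times[seq_len(nr)]))
  zscore_event_maps(power_list, params$freqs, fs, baseline_ms)
}

#' Significance mask of a Z-scored map
#'
#' @param tf a zscore-mode `tf_map`.
#' @param z_crit critical value (default 3.09, i.e. `P < 0.001`).
#' @param tail `"two"` masks `|Z| > z_crit`; `"one"` masks `Z > z_crit`.
#' @return A logical matrix, TRUE only at valid samples beyond the cutoff.
#' @export
significant_tf_mask <- function(tf, z_crit = 3.09, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (tf$mode != "zscore") stop_fmt("significant_tf_mask: need a zscore map")
  z <- tf$values
  m <- if (tail == "two") abs(z) > z_crit else z > z_crit
  m & tf$valid & !is.na(z)
}

#' Peak pre-ID high-frequency-oscillation score
#'
#' Maximum Z over a frequency band crossed with a peri-event window
#' (defaults: 40-120 Hz in the pre-ID window), with its location.
#'
#' @param tf a zscore-mode `tf_map` with relative times.
#' @param band_hz frequency band, Hz.
#' @param window_ms peri-event window, ms relative to the peak.
#' @return A list `peak_z`, `peak_freq_hz`, `peak_time_ms`.
#' @export
preid_hfo_score <- function(tf, band_hz = c(40, 120), window_ms = c(-300, -50)) {
  if (tf$mode != "zscore") stop_fmt("preid_hfo_score: need a zscore map")
  jj <- which(tf$freqs >= band_hz[1] & tf$freqs <= band_hz[2])
  ii <- which(tf$times >= window_ms[1] / 1000 & tf$times < window_ms[2] / 1000)
  if (!length(jj) || !length(ii))
    stop_fmt("preid_hfo_score: band/window outside the analysed map")
  sub <- tf$values[ii, jj, drop = FALSE]
  sub[!tf$valid[ii, jj, drop = FALSE]] <- -Inf
  k <- which.max(sub)
  ri <- (k - 1L) %% length(ii) + 1L
  ci <- (k - 1L) %/% length(ii) + 1L
  list(peak_z = sub[ri, ci], peak_freq_hz = tf$freqs[jj[ci]],
       peak_time_ms = tf$times[ii[ri]] * 1000)
}

#' Normality check of wavelet coefficients (Lilliefors)
#'
#' One-sample Kolmogorov-Smirnov test against a normal distribution with
#' the sample's own mean and SD, using Lilliefors critical values (the
#' reference parameters are estimated, so the plain KS null would be
#' anti-conservative).
#'
#' @param values numeric sample (length >= 10, non-constant).
#' @param alpha rejection level.
#' @return A list `D`, `p`, `reject`.
#' @export
ks_normality <- function(values, alpha = 0.05) {
  if (length(values) < 10) stop_fmt("ks_normality: need >= 10 values")
  if (stats::sd(values) == 0) stop_fmt("ks_normality: constant sample")
  lt <- nortest::lillie.test(values)
  list(D = unname(lt$statistic), p = lt$p.value, reject = lt$p.value < alpha)
}

#' Plot a time-frequency map
#' @param x a `tf_map`.
#' @param ... passed to [graphics::image].
#' @export
plot.tf_map <- function(x, ...) {
  v <- x$values
  v[!x$valid] <- NA
  graphics::image(x$times, x$freqs, v, xlab = "time (s)",
                  ylab = "frequency (Hz)", ...)
  invisible(x)
}
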