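# Threshold-based interictal discharge (ID) detection in the LFP.
#
# IDs present as a pointed peak with large amplitude, large slope and a
# sharp component lasting 20-100 ms, in either polarity. "Large" is defined
# against robust background statistics (median / scaled MAD), so the
# discharges themselves do not inflate the reference scale.

#' Detector parameters
#'
#' @param amp_k amplitude threshold in robust-SD units of the (detrended)
#'   trace. Default 6: pure-Gaussian false positives are far below 1/min at
#'   1 kHz.
#' @param slope_k slope threshold in robust-SD units of the lagged trace
#'   difference (see `slope_step_ms`).
#' @param slope_step_ms step (ms) over which the slope is measured. The
#'   per-sample first difference of a band-limited 20-100 ms transient is
#'   negligible against broadband noise at 1 kHz, so steepness is judged on
#'   a 10-ms step by default, where a sharp discharge component stands well
#'   above the background slope scale.
#' @param dur_min_ms,dur_max_ms admissible duration (ms) of the sharp
#'   component, measured between the amplitude-threshold crossings that
#'   bound the peak.
#' @param refractory_ms minimum inter-peak separation; closer events are
#'   merged keeping the larger-amplitude peak, so a spike-and-slow-wave
#'   complex yields one event.
#' @param gap_ms suprathreshold runs separated by less than this are fused
#'   before the duration test (noise riding on a discharge can split the
#'   crossing into fragments).
#' @return A `detector_params` list.
#' @export
detector_params <- function(amp_k = 6, slope_k = 3, slope_step_ms = 10,
                            dur_min_ms = 20, dur_max_ms = 100,
                            refractory_ms = 300, gap_ms = 10) {
  stopifnot(amp_k > 0, slope_k > 0, slope_step_ms >= 1,
            dur_min_ms < dur_max_ms, gap_ms >= 0)
  structure(list(amp_k = amp_k, slope_k = slope_k,
                 slope_step_ms = slope_step_ms, dur_min_ms = dur_min_ms,
                 dur_max_ms = dur_max_ms, refractory_ms = refractory_ms,
                 gap_ms = gap_ms),
            class = "detector_params")
}

#' Robust background statistics of an LFP trace
#'
#' Median/MAD-based centre and scale, computed over the whole trace: the
#' medians tolerate contamination by the discharges themselves, so nothing
#' is excluded.
#'
#' @param lfp an [lfp_signal] with at least 1000 samples.
#' @param slope_step_ms step (ms) of the lagged difference whose robust SD
#'   becomes `slope_scale`.
#' @return A list with `center` (median, uV), `scale` (1.4826 x MAD, uV)
#'   and `slope_scale` (robust SD of the trace difference over
#'   `slope_step_ms`), plus a `degenerate` flag when the scale is zero.
#' @export
background_stats <- function(lfp, slope_step_ms = 10) {
  x <- lfp$samples
  if (length(x) < 1000) stop_fmt("background_stats: need >= 1000 samples")
  center <- stats::median(x)
  scale <- stats::mad(x, center = center)        # 1.4826 * MAD
  step <- max(1L, round(slope_step_ms / 1000 * lfp$fs))
  slope_scale <- stats::mad(diff(x, lag = step))
  structure(list(center = center, scale = scale, slope_scale = slope_scale,
                 degenerate = scale <= 0),
            class = "background_stats")
}

#' Prepare an LFP trace for detection and spectral analysis
#'
#' Decimates to `target_fs` (default 1 kHz) after a 300-Hz low-pass
#' anti-alias filter, then removes slow drift by subtracting a 2-s moving
#' median. Subtracting a running median preserves sharp-transient
#' morphology better than band-pass filtering. Traces already at or below
#' `target_fs` are only detrended.
#'
#' @param lfp an [lfp_signal].
#' @param target_fs target sampling rate (Hz); the decimation factor
#'   `fs / target_fs` must be an integer.
#' @param detrend_s moving-median window in seconds (0 disables).
#' @param lowpass_hz anti-alias cut-off used when decimating.
#' @return The prepared [lfp_signal].
#' @export
prepare_lfp <- function(lfp, target_fs = 1000, detrend_s = 2, lowpass_hz = 300) {
  x <- lfp$samples
  fs <- lfp$fs
  if (fs > target_fs) {
    fac <- fs / target_fs
    if (abs(fac - round(fac)) > 1e-8)
      stop_fmt("prepare_lfp: fs %g is not an integer multiple of %g", fs, target_fs)
    fac <- as.integer(round(fac))
    bf <- signal::butter(4, min(lowpass_hz / (fs / 2), 0.99), type = "low")
    x <- signal::filtfilt(bf, x)
    x <- x[seq(1L, length(x), by = fac)]
    fs <- target_fs
  }
  if (detrend_s > 0 && length(x) > 3) {
    k <- min(2L * floor(detrend_s * fs / 2) + 1L, 2L * floor((length(x) - 1) / 2) + 1L)
    if (k >= 3) x <- x - stats::runmed(x, k, endrule = "median")
  }
  lfp_signal(x, fs, lfp$channel_id, lfp$t0)
}

#' Detect interictal discharges by amplitude/slope/duration criteria
#'
#' A candidate is a contiguous run of samples whose absolute deviation from
#' the background centre exceeds `amp_k` robust SDs (both polarities), whose
#' maximal absolute first difference exceeds `slope_k` robust slope SDs, and
#' whose duration at the amplitude crossing falls within
#' `[dur_min_ms, dur_max_ms]`. Candidates closer than `refractory_ms` are
#' merged keeping the larger-amplitude peak.
#'
#' The trace is prepared with [prepare_lfp] first unless `prepare = FALSE`.
#'
#' @param lfp an [lfp_signal] with `fs >= 200` Hz.
#' @param params a [detector_params] list.
#' @param prepare logical; decimate/detrend before detection.
#' @return An [event_set] (source `"detected"`) with onset/offset at the
#'   threshold crossings and signed `peak_amplitude` relative to the centre.
#' @export
detect_ids <- function(lfp, params = detector_params(), prepare = TRUE) {
  if (lfp$fs < 200) stop_fmt("detect_ids: fs must be >= 200 Hz")
  work <- if (prepare) prepare_lfp(lfp) else lfp
  bg <- background_stats(work, slope_step_ms = params$slope_step_ms)
  if (bg$degenerate) stop_fmt("detect_ids: degenerate background (zero scale)")
  fs <- work$fs
  dev <- abs(work$samples - bg$center)
  above <- dev > params$amp_k * bg$scale
  # fuse runs separated by < gap_ms before applying the duration filter
  if (params$gap_ms > 0 && any(above)) {
    r <- rle(above)
    gap_n <- params$gap_ms / 1000 * fs
    short_gap <- !r$values & r$lengths < gap_n
    # gaps at the edges stay gaps
    if (length(short_gap)) short_gap[c(1L, length(short_gap))] <- FALSE
    r$values[short_gap] <- TRUE
    above <- inverse.rle(r)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  step <- max(1L, round(params$slope_step_ms / 1000 * fs))
  slopes <- abs(diff(work$samples, lag = step))
  peaks <- onsets <- offsets <- amps <- numeric(0)
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    dur_ms <- (i1 - i0 + 1L) / fs * 1000
    if (dur_ms < params$dur_min_ms || dur_ms > params$dur_max_ms) next
    # slope window: differences touching the run
    s0 <- max(1L, i0 - step); s1 <- min(length(slopes), i1)
    smax <- if (s1 >= s0) max(slopes[s0:s1]) else 0
    if (smax <= params$slope_k * bg$slope_scale) next
    ipk <- i0 - 1L + which.max(dev[i0:i1])   # ties -> earliest
    peaks <- c(peaks, ipk); onsets <- c(onsets, i0); offsets <- c(offsets, i1)
    amps <- c(amps, work$samples[ipk] - bg$center)
  }
  # merge events closer than refractory_ms, keeping the larger |amplitude|
  if (length(peaks) > 1) {
    refr_n <- params$refractory_ms / 1000 * fs
    keep_i <- 1L
    sel <- integer(0)
    for (j in 2:length(peaks)) {
      if (peaks[j] - peaks[keep_i] < refr_n) {
        if (abs(amps[j]) > abs(amps[keep_i])) keep_i <- j
      } else {
        sel <- c(sel, keep_i); keep_i <- j
      }
    }
    sel <- c(sel, keep_i)
    peaks <- peaks[sel]; onsets <- onsets[sel]; offsets <- offsets[sel]
    amps <- amps[sel]
  }
  t_of <- function(i) work$t0 + (i - 1L) / fs   # R index -> time (0-based samples)
  event_set(peak_time = t_of(peaks), onset = t_of(onsets), offset = t_of(offsets),
            peak_amplitude = amps, channel_id = work$channel_id,
            source = "detected")
}

#' Align events on the sharpest peak
#'
#' Moves each event's `peak_time` to the sample of maximal absolute
#' deviation from the background centre within `[onset, offset]`; ties go
#' to the earliest sample.
#'
#' @param events an [event_set] whose `[onset, offset]` intervals lie
#'   inside the trace.
#' @param lfp the [lfp_signal] the events refer to (same time base).
#' @return The re-aligned [event_set].
#' @export
align_events <- function(events, lfp) {
  if (!nrow(events)) return(events)
  bg <- background_stats(lfp)
  fs <- lfp$fs
  n <- length(lfp$samples)
  pk <- events$peak_time; amp <- events$peak_amplitude
  for (i in seq_len(nrow(events))) {
    i0 <- round((events$onset[i] - lfp$t0) * fs) + 1L
    i1 <- round((events$offset[i] - lfp$t0) * fs) + 1L
    if (i0 < 1L || i1 > n) stop_fmt("align_events: event %d outside trace", i)
    seg <- abs(lfp$samples[i0:i1] - bg$center)
    ipk <- i0 - 1L + which.max(seg)
    pk[i] <- lfp$t0 + (ipk - 1L) / fs
    amp[i] <- lfp$samples[ipk] - bg$center
  }
  event_set(peak_time = pk, onset = events$onset, offset = events$offset,
            peak_amplitude = amp, channel_id = events$channel_id,
            source = attr(events, "source"))
}

#' Event-rate statistics over 60-s epochs
#'
#' @param events an [event_set].
#' @param span numeric `[start, end]` interval in seconds.
#' @param epoch_s epoch length for the dispersion statistics.
#' @return A list with `mean_hz` (count / span length), and `sd_hz`,
#'   `min_hz`, `max_hz` over non-overlapping epochs (`NA` when the span is
#'   shorter than one epoch).
#' @export
event_rate <- function(events, span, epoch_s = 60) {
  len <- diff(span)
  if (len <= 0) stop_fmt("event_rate: span length must be > 0")
  mean_hz <- nrow(events) / len
  n_ep <- floor(len / epoch_s)
  if (n_ep < 1) {
    return(list(mean_hz = mean_hz, sd_hz = NA_real_, min_hz = NA_real_,
                max_hz = NA_real_, n_epochs = 0L))
  }
  edges <- span[1] + epoch_s * (0:n_ep)
  counts <- tabulate(findInterval(events$peak_time, edges,
                                  rightmost.closed = FALSE),
                     nbins = n_ep + 1L)[seq_len(n_ep)]
  rates <- counts / epoch_s
  list(mean_hz = mean_hz,
       sd_hz = if (n_ep > 1) stats::sd(rates) else NA_real_,
       min_hz = min(rates), max_hz = max(rates), n_epochs = n_ep)
}
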