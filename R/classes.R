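# Core domain containers: LFP traces, spike trains, event sets.

#' Construct an LFP signal
#'
#' A uniformly sampled voltage trace. The time of sample `i` (0-based) is
#' `t0 + i / fs`.
#'
#' @param samples numeric vector of voltages in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_id character channel label.
#' @param t0 start time in seconds.
#' @return An object of class `lfp_signal`.
#' @export
lfp_signal <- function(samples, fs, channel_id = "ch1", t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(fs), length(fs) == 1L, fs > 0)
  structure(list(channel_id = as.character(channel_id), fs = as.numeric(fs),
                 t0 = as.numeric(t0), samples = as.numeric(samples)),
            class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("<lfp_signal> channel %s: %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              x$channel_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$t0))
  invisible(x)
}

# sample times of an lfp_signal
lfp_times <- function(lfp) lfp$t0 + (seq_along(lfp$samples) - 1) / lfp$fs

# crop to [from, to) by sample time; returns lfp_signal with adjusted t0
lfp_crop <- function(lfp, from, to) {
  i0 <- max(0L, ceiling((from - lfp$t0) * lfp$fs - 1e-9))
  i1 <- min(length(lfp$samples) - 1L, floor((to - lfp$t0) * lfp$fs - 1e-9))
  if (i1 < i0) stop_fmt("empty crop window [%g, %g)", from, to)
  lfp_signal(lfp$samples[(i0 + 1L):(i1 + 1L)], lfp$fs, lfp$channel_id,
             t0 = lfp$t0 + i0 / lfp$fs)
}

#' Construct a spike train
#'
#' Sorted single-unit event times over a known recording span.
#'
#' @param times numeric spike times in seconds, strictly increasing.
#' @param span numeric length-2 recording interval `[start, end]` in seconds.
#' @param unit_id,channel_id character labels.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, span = NULL, unit_id = "u1", channel_id = "ch1") {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    ord <- sort(times)
    dup <- duplicated(ord)
    if (any(dup)) {
      warn_fmt("unit %s: %d duplicate spike time(s) collapsed", unit_id, sum(dup))
      ord <- ord[!dup]
    }
    times <- ord
  }
  if (is.null(span)) span <- c(0, if (length(times)) max(times) else 1)
  stopifnot(length(span) == 2L, span[2] > span[1])
  if (length(times) && (times[1] < span[1] || times[length(times)] > span[2]))
    stop_fmt("unit %s: spike times outside span [%g, %g]", unit_id, span[1], span[2])
  structure(list(unit_id = as.character(unit_id),
                 channel_id = as.character(channel_id),
                 times = times, span = as.numeric(span)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s (channel %s): %d spikes over [%g, %g] s (%.2f Hz)\n",
              x$unit_id, x$channel_id, length(x$times), x$span[1], x$span[2],
              length(x$times) / diff(x$span)))
  invisible(x)
}

#' Construct an event set
#'
#' Interictal-discharge events characterised by a peak time with onset and
#' offset bounds and a peak amplitude.
#'
#' @param peak_time,onset,offset numeric vectors in seconds
#'   (`onset <= peak <= offset` per event; peaks strictly increasing).
#' @param peak_amplitude numeric peak amplitudes in microvolts (signed,
#'   relative to the background centre).
#' @param channel_id character label(s), recycled.
#' @param source `"detected"` or `"imported"`.
#' @return An object of class `event_set` (a data frame).
#' @export
event_set <- function(peak_time = numeric(), onset = peak_time,
                      offset = peak_time, peak_amplitude = rep(NA_real_, length(peak_time)),
                      channel_id = "ch1", source = c("detected", "imported")) {
  source <- match.arg(source)
  n <- length(peak_time)
  df <- data.frame(channel_id = rep_len(as.character(channel_id), n),
                   peak_time = as.numeric(peak_time),
                   onset = as.numeric(onset), offset = as.numeric(offset),
                   peak_amplitude = as.numeric(rep_len(peak_amplitude, n)))
  if (n) {
    ord <- order(df$peak_time)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    if (any(diff(df$peak_time) <= 0))
      stop_fmt("event peak times must be strictly increasing")
    if (any(df$onset > df$peak_time | df$peak_time > df$offset))
      stop_fmt("event onset <= peak <= offset violated")
  }
  structure(df, class = c("event_set", "data.frame"), source = source)
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d event(s), source: %s\n", nrow(x), attr(x, "source")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

n_events <- function(events) nrow(events)
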