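# Unit quality filtering, instantaneous rate estimation, peri-event
# rasters/histograms, and per-unit modulation classification over the
# baseline / pre-ID / ID / post-ID windows.

#' Peri-event analysis windows
#'
#' Windows are stored in milliseconds relative to the event peak, half-open
#' `[a, b)`: baseline `[-600, -300)`, pre-ID `[-300, -50)`, ID `[-50, 50)`,
#' post-ID `[50, 400)`; rasters span +/- 1000 ms.
#'
#' @param baseline,pre_id,id,post_id numeric length-2 windows in ms.
#' @param raster_halfwidth_ms raster half-width in ms.
#' @return A `peri_event_windows` list.
#' @export
peri_event_windows <- function(baseline = c(-600, -300), pre_id = c(-300, -50),
                               id = c(-50, 50), post_id = c(50, 400),
                               raster_halfwidth_ms = 1000) {
  w <- list(baseline = baseline, pre_id = pre_id, id = id, post_id = post_id)
  for (nm in names(w)) {
    stopifnot(length(w[[nm]]) == 2L, w[[nm]][1] < w[[nm]][2],
              w[[nm]][1] >= -raster_halfwidth_ms,
              w[[nm]][2] <= raster_halfwidth_ms)
  }
  # pairwise disjoint
  ord <- w[order(vapply(w, `[`, 0, 1))]
  for (i in seq_len(length(ord) - 1))
    if (ord[[i]][2] > ord[[i + 1]][1]) stop_fmt("peri-event windows overlap")
  c(w, list(raster_halfwidth_ms = raster_halfwidth_ms))
}

#' Fraction of inter-spike intervals violating a refractory period
#'
#' Spike-sorting quality criterion: units are admitted when fewer than 0.5%
#' of inter-spike intervals fall within a 1-ms refractory period.
#'
#' @param train a [spike_train].
#' @param refractory_ms refractory period in ms.
#' @return Fraction in `[0, 1]`; 0 for trains with fewer than 2 spikes.
#' @export
isi_violation_fraction <- function(train, refractory_ms = 1) {
  if (length(train$times) < 2) return(0)
  isi <- diff(train$times)
  mean(isi < refractory_ms / 1000)
}

#' Does a unit pass the ISI quality filter?
#' @inheritParams isi_violation_fraction
#' @param max_fraction admissible violation fraction (default 0.005).
#' @return Logical.
#' @export
passes_isi_filter <- function(train, refractory_ms = 1, max_fraction = 0.005) {
  isi_violation_fraction(train, refractory_ms) < max_fraction
}

#' Instantaneous firing rate by Gaussian kernel smoothing
#'
#' Convolves the spike times with a Gaussian of standard deviation
#' `sigma_ms` (area one per spike), sampled every `dt_ms`. The support is
#' padded by 5 sigma on each side so the trace integrates to the spike
#' count. Each spike's kernel is renormalised on the truncated support, so
#' the integral identity holds to numerical precision.
#'
#' @param train a [spike_train].
#' @param sigma_ms kernel SD in ms (default 20, near the modal ISI).
#' @param dt_ms sample step in ms.
#' @return A `rate_trace` list with `t_start`, `dt` (s) and `values` (Hz).
#' @export
instantaneous_rate <- function(train, sigma_ms = 20, dt_ms = 1) {
  stopifnot(sigma_ms > 0, dt_ms > 0)
  sigma <- sigma_ms / 1000; dt <- dt_ms / 1000
  pad <- 5 * sigma
  t0 <- train$span[1] - pad
  n <- ceiling((train$span[2] + pad - t0) / dt) + 1L
  vals <- numeric(n)
  if (length(train$times)) {
    half <- ceiling(pad / dt)
    koff <- (-half:half) * dt
    for (s in train$times) {
      j0 <- round((s - t0) / dt)          # 0-based index of nearest grid point
      frac <- s - (t0 + j0 * dt)
      k <- stats::dnorm(koff - frac, sd = sigma)
      k <- k / (sum(k) * dt)              # exact unit area on the grid
      jj <- j0 + (-half:half) + 1L
      ok <- jj >= 1L & jj <= n
      vals[jj[ok]] <- vals[jj[ok]] + k[ok]
    }
  }
  structure(list(t_start = t0, dt = dt, values = vals), class = "rate_trace")
}

#' Peri-event raster of spike latencies
#'
#' Latencies (ms) of spikes relative to each event peak, within the
#' half-open window `[-halfwidth, +halfwidth)`. Events whose window exceeds
#' the recording span are dropped and counted.
#'
#' @param train a [spike_train].
#' @param events an [event_set].
#' @param halfwidth_ms raster half-width in ms (default 1000).
#' @return A `peri_event_raster`: list of per-event latency vectors (ms)
#'   plus `unit_id`, `n_events`, `halfwidth_ms`, `n_dropped`.
#' @export
peri_event_raster <- function(train, events, halfwidth_ms = 1000) {
  hw <- halfwidth_ms / 1000
  pk <- events$peak_time
  ok <- pk - hw >= train$span[1] & pk + hw <= train$span[2]
  n_dropped <- sum(!ok)
  pk <- pk[ok]
  tt <- train$times
  lat <- vector("list", length(pk))
  if (length(pk)) {
    lo <- findInterval(pk - hw, tt, left.open = TRUE) + 1L
    hi <- findInterval(pk + hw, tt, left.open = TRUE)
    for (i in seq_along(pk)) {
      lat[[i]] <- if (hi[i] >= lo[i])
        (tt[lo[i]:hi[i]] - pk[i]) * 1000 else numeric(0)
      # enforce half-open right edge
      lat[[i]] <- lat[[i]][lat[[i]] < halfwidth_ms & lat[[i]] >= -halfwidth_ms]
    }
  }
  structure(list(unit_id = train$unit_id, latencies = lat,
                 n_events = length(pk), halfwidth_ms = halfwidth_ms,
                 n_dropped = n_dropped),
            class = "peri_event_raster")
}

#' @export
print.peri_event_raster <- function(x, ...) {
  cat(sprintf("<peri_event_raster> unit %s: %d events, %d spikes in +/-%g ms (%d event(s) dropped)\n",
              x$unit_id, x$n_events, sum(lengths(x$latencies)),
              x$halfwidth_ms, x$n_dropped))
  invisible(x)
}

#' Peri-event time histogram (PSTH)
#'
#' @param raster a [peri_event_raster].
#' @param bin_ms bin width in ms; must divide the raster width evenly.
#' @return A data frame with `t_ms` (bin left edge), `count`, `rate_hz`
#'   (count / (n_events * bin width)).
#' @export
psth <- function(raster, bin_ms = 10) {
  width <- 2 * raster$halfwidth_ms
  if (abs(width / bin_ms - round(width / bin_ms)) > 1e-9)
    stop_fmt("psth: bin_ms must divide %g ms evenly", width)
  nb <- as.integer(round(width / bin_ms))
  edges <- -raster$halfwidth_ms + bin_ms * (0:nb)
  lat <- unlist(raster$latencies)
  counts <- if (length(lat))
    tabulate(findInterval(lat, edges, rightmost.closed = FALSE), nbins = nb)
  else integer(nb)
  rate <- if (raster$n_events > 0) counts / (raster$n_events * bin_ms / 1000)
  else rep(0, nb)
  data.frame(t_ms = edges[-(nb + 1L)], count = counts, rate_hz = rate)
}

# per-event spike counts in a window (ms, half-open) of a raster
window_counts <- function(raster, win) {
  vapply(raster$latencies, function(l) sum(l >= win[1] & l < win[2]), 0L)
}

#' Classify peri-event firing-rate modulation of one unit
#'
#' Window rates are raw counts pooled across events divided by
#' `n_events * window length` (the smoothed rate trace is not used: a 20-ms
#' kernel would leak across the 100-ms ID window). Classes:
#' \itemize{
#'   \item `class_id = "increase"` iff ID/baseline rate ratio >= 2;
#'   \item `class_post = "decrease"` iff post-ID/baseline ratio <= 0.5;
#'   \item `class_pre` is `"increase"`/`"decrease"` iff a per-unit paired
#'     two-sided t-test across events (per-event pre-ID rate vs per-event
#'     baseline rate) has `p < alpha`, direction by the sign of the mean
#'     difference.
#' }
#' With a silent baseline, ratios are computed with a floor of `eps_hz`
#' added to numerator and denominator and the result is flagged.
#'
#' @param raster a [peri_event_raster].
#' @param windows a [peri_event_windows] list.
#' @param alpha significance level of the per-unit pre-ID test.
#' @param eps_hz rate floor used when the baseline rate is zero.
#' @param min_events minimum number of events required.
#' @return A one-row data frame (`modulation_result`): per-window rates,
#'   ratios, classes, the pre-ID test statistic/p, and flags.
#' @export
classify_modulation <- function(raster, windows = peri_event_windows(),
                                alpha = 0.05, eps_hz = 0.1, min_events = 10) {
  if (raster$n_events < min_events)
    stop_fmt("classify_modulation: need >= %d events (have %d)",
             min_events, raster$n_events)
  wl <- function(w) diff(w) / 1000                   # window length in s
  cnt <- lapply(windows[c("baseline", "pre_id", "id", "post_id")],
                function(w) window_counts(raster, w))
  rate <- vapply(names(cnt), function(nm)
    sum(cnt[[nm]]) / (raster$n_events * wl(windows[[nm]])), 0)
  floored <- rate[["baseline"]] == 0
  rr <- function(nm) {
    if (floored) (rate[[nm]] + eps_hz) / (rate[["baseline"]] + eps_hz)
    else rate[[nm]] / rate[["baseline"]]
  }
  ratio_id <- rr("id"); ratio_pre <- rr("pre_id"); ratio_post <- rr("post_id")
  # per-event rates for the paired pre-ID test
  pre_rates <- cnt$pre_id / wl(windows$pre_id)
  base_rates <- cnt$baseline / wl(windows$baseline)
  d <- pre_rates - base_rates
  if (stats::sd(d) == 0) {
    t_pre <- 0; p_pre <- if (all(d == 0)) 1 else 0
    pre_flag <- TRUE
  } else {
    tt <- stats::t.test(pre_rates, base_rates, paired = TRUE)
    t_pre <- unname(tt$statistic); p_pre <- tt$p.value
    pre_flag <- FALSE
  }
  class_pre <- if (p_pre < alpha && mean(d) != 0) {
    if (mean(d) > 0) "increase" else "decrease"
  } else "none"
  data.frame(unit_id = raster$unit_id,
             rate_baseline = rate[["baseline"]], rate_pre = rate[["pre_id"]],
             rate_id = rate[["id"]], rate_post = rate[["post_id"]],
             ratio_id = ratio_id, ratio_pre = ratio_pre, ratio_post = ratio_post,
             class_id = if (ratio_id >= 2) "increase" else "none",
             class_post = if (ratio_post <= 0.5) "decrease" else "none",
             class_pre = class_pre,
             t_pre = t_pre, p_pre = p_pre,
             baseline_floored = floored, pre_test_degenerate = pre_flag,
             n_events = raster$n_events,
             stringsAsFactors = FALSE)
}

#' Group-level one-sample t-test on per-unit rate differences
#'
#' Tests whether the mean per-unit difference (window minus baseline) is
#' shifted from zero; one-tailed, with `df = n - 1` as in paired group
#' comparisons across units.
#'
#' @param window_rates,baseline_rates paired per-unit mean rates (Hz).
#' @param tail `"right"` (increase) or `"left"` (decrease).
#' @return A list with `t`, `p`, `df`, and a `degenerate` flag for
#'   zero-variance differences (p is then 0 or 1 by the sign of the mean).
#' @export
group_rate_test <- function(window_rates, baseline_rates,
                            tail = c("right", "left")) {
  tail <- match.arg(tail)
  stopifnot(length(window_rates) == length(baseline_rates),
            length(window_rates) >= 2)
  d <- window_rates - baseline_rates
  n <- length(d); df <- n - 1L
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, p = 0.5, df = df, degenerate = TRUE))
    p <- if ((tail == "right") == (mean(d) > 0)) 0 else 1
    return(list(t = sign(mean(d)) * Inf, p = p, df = df, degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  p <- stats::pt(t, df, lower.tail = (tail == "left"))
  list(t = t, p = p, df = df, degenerate = FALSE)
}

#' Plot a peri-event raster with its PSTH
#'
#' @param x a [peri_event_raster].
#' @param bin_ms PSTH bin width in ms.
#' @param ... passed to [graphics::plot].
#' @export
plot.peri_event_raster <- function(x, bin_ms = 10, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-x$halfwidth_ms, x$halfwidth_ms),
                 ylim = c(0, max(1, x$n_events)),
                 xlab = "", ylab = "event", ...)
  for (i in seq_along(x$latencies))
    if (length(x$latencies[[i]]))
      graphics::points(x$latencies[[i]], rep(i, length(x$latencies[[i]])),
                       pch = ".", cex = 2)
  graphics::abline(v = 0, col = "red", lty = 2)
  h <- psth(x, bin_ms)
  graphics::plot(h$t_ms + bin_ms / 2, h$rate_hz, type = "s",
                 xlab = "time from ID peak (ms)", ylab = "rate (Hz)")
  graphics::abline(v = 0, col = "red", lty = 2)
  invisible(x)
}
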