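---
title: "Methods: peri-event analysis of interictal discharges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-event analysis of interictal discharges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(iedflow)
```

This vignette documents the models and procedures implemented in
`iedflow`, the assumptions behind them, the numerical and design choices
made where the problem was genuinely open, and what the synthetic-data
validation does and does not establish about real recordings.

## The scientific setting

Interictal epileptiform discharges (IDs) are transient pathological LFP
events between seizures: a sharp, pointed component of roughly 20–100 ms,
often followed by a slow wave of 200–500 ms. In microelectrode recordings
from epileptic hippocampus or entorhinal cortex they recur sporadically
(on the order of 0.01–0.2 Hz). The questions this package addresses are:
which single units change their firing around the discharge and when
(before, during, after); whether the pre-discharge LFP carries
high-frequency (40–120 Hz) oscillations; and whether unit pairs co-fire
at millisecond precision beyond what their slow rate changes explain.

All times are seconds internally; window and kernel parameters are
accepted in milliseconds and converted once. Samples are indexed from 0
and every time window is half-open `[a, b)`, so boundary spikes are
counted exactly once.

## Discharge detection

`detect_ids()` operates on the broadband trace after two preparation
steps (`prepare_lfp()`): decimation to 1 kHz behind a 300-Hz Butterworth
anti-alias filter — the LFP band of interest lies below 300 Hz — and
subtraction of a 2-s moving median, which removes drift while preserving
sharp-transient morphology better than a band-pass would.

Background statistics are medians: centre = median, scale
$\hat\sigma = 1.4826\,\mathrm{MAD}$, so the discharges themselves do not
inflate the reference scale and nothing needs to be excluded. A candidate
event is a contiguous run with $|v - \mathrm{centre}| > k_a\hat\sigma$
(both polarities; runs separated by less than `gap_ms` = 10 ms are fused
first, because noise riding on a large transient fragments the crossing).
The run must satisfy two further criteria:

* **Duration.** The crossing width must lie within 20–100 ms. The width
  is measured between the threshold crossings bounding the peak, not over
  the full wave, because the 20–100 ms figure describes the rapid
  component. Note a consequence: a blunt wave rejected "by duration" must
  stay above threshold for more than 100 ms; the sharp/blunt distinction
  is made at the detection threshold, not at the waveform's base.
* **Slope.** The maximal absolute trace difference over a
  `slope_step_ms` = 10 ms step must exceed $k_s$ times the robust SD of
  that same lagged difference. A per-sample first difference would be
  useless here: at 1 kHz the sample-to-sample increment of any
  band-limited 20–100 ms transient is a fraction of the broadband noise
  increment, so steepness has to be judged at the timescale of the rising
  phase. At the defaults, an SNR-8 template's 10-ms slope is ≈ 3.5× the
  background slope scale, hence `slope_k = 3`.

Defaults `amp_k = 6`, `slope_k = 3` are engineering choices (thresholds
of this kind are rarely published with the data); at `amp_k = 6` the
expected false-positive rate on Gaussian noise is far below one per
minute at 1 kHz. Events closer than `refractory_ms` = 300 ms merge,
keeping the larger-amplitude peak, so a spike-and-slow-wave complex
yields one event. `align_events()` then moves each peak to the sample of
maximal absolute deviation within the event, ties to the earliest sample.
Detection is invariant to adding a constant and equivariant under sign
flip, and raising `amp_k` can only remove events.

A degenerate background (constant trace, scale 0) is refused rather than
guessed at: every sample or none would cross the threshold.

## Peri-event unit analysis

Units enter the analysis only if fewer than 0.5% of their inter-spike
intervals fall below 1 ms (`passes_isi_filter()`), the usual
sorting-quality criterion. The instantaneous rate
(`instantaneous_rate()`) convolves spike times with a Gaussian of
$\sigma$ = 20 ms — close to the modal ISI — with unit area per spike; the
kernel is renormalised on its truncated ±5σ support so the trace
integrates to the spike count to numerical precision (this identity is a
standing test).

Rasters collect latencies in the half-open ±1 s window; events whose
window leaves the recording are dropped and counted, never silently.
PSTHs use 10-ms bins; bin counts and raster counts agree exactly.

Modulation classification (`classify_modulation()`) uses **raw counts**
per window, not the smoothed trace: a 20-ms kernel would leak across the
100-ms ID window. Per-window rate = pooled spikes / (events × window
length). Classes:

* `class_id = "increase"` iff ID/baseline ≥ 2,
* `class_post = "decrease"` iff post-ID/baseline ≤ 0.5,
* `class_pre` by a per-unit paired two-sided t-test across events
  (per-event pre-ID rate vs per-event baseline rate) at α = 0.05,
  direction from the sign of the mean difference.

The pre-ID rule is an interpretation: a per-unit significance criterion
is needed and the across-event pairing matches the variance structure the
rasters expose, but other reasonable tests exist; the result row carries
the test statistic and p so users can re-threshold. The ratio rules and
the significance rule are reported separately rather than conflated,
since whether the ID-increase class additionally required a per-unit test
is not decidable from published summaries.

A silent baseline would make ratios infinite; instead a floor of
ε = 0.1 Hz is added to numerator and denominator and the row is flagged.
The floor is negligible at the rate scales the windows are designed for
(≥ 1 Hz) and only stabilises pathological cases.

Group-level tests (`group_rate_test()`) are one-sample t-tests on
per-unit differences with df = n − 1, one-tailed in the direction under
test — the degrees of freedom printed in group comparisons of this kind
equal group size minus one, which identifies the paired one-sample form.
Zero-variance differences yield p ∈ {0, 1} by sign (flagged), or p = 0.5
when all differences vanish.

## Morlet time–frequency maps

The complex Morlet wavelet is
$\Psi_{\tau,f}(u) = f\, e^{j 2\pi f (u-\tau)}\, e^{-(u-\tau)^2/2\sigma^2}$
with $\sigma = n_{co}/(6f)$ and $n_{co} = 5$; power is $|W|^2$. With the
prefactor $f$, the tone response $f\sigma(f)\sqrt{2\pi}$ is flat in
frequency, so a pure tone's power peaks exactly at the tone frequency —
with a $\sqrt f$ prefactor the peak would sit visibly below it (by about
$f/55$, i.e. ≈ 1.5 Hz at 80 Hz), which would violate the package's own
localisation test. Kernels are truncated at ±5σ; samples within half a
kernel of an edge are flagged invalid and never enter baselines, masks or
scores.

Baseline normalisation (`baseline_zscore()`, `event_tf_zscore()`): per
frequency, the mean and SD of power are pooled over all events' baseline
windows (−600..−300 ms before the peak), the whole peri-event map becomes
$Z = (P - \mu)/s$, and maps are averaged across events *after*
normalisation. Pooling across events (rather than per-event
normalisation) stabilises the SD estimate at realistic event counts. The
Z-map is invariant to rescaling the LFP; power maps are 2-homogeneous.
`event_tf_zscore()` transforms padded per-event segments, so memory does
not grow with recording length.

The significance cutoff is $|Z| > 3.09$, the two-sided reading of the
$P < 0.001$ normal tail; whether the published criterion was one- or
two-tailed is ambiguous ("absolute values" paired with a one-tailed
critical value), so `significant_tf_mask()` exposes both and defaults to
$|Z|$. `preid_hfo_score()` reports the maximal Z over 40–120 Hz × pre-ID
with its location. Normality of coefficients is checked with the
Lilliefors form of the KS test (`nortest::lillie.test`): the reference
normal's parameters are estimated from the sample, so plain KS critical
values would be anti-conservative.

## Surrogate synchrony tests

Two complementary null models, both implemented in compiled code with all
randomness drawn from R's RNG (bit-reproducible under a seed; each pair's
stream is derived from the master seed and the unit ids, so results do
not depend on analysis order):

* **Jittered cross-correlograms.** Counts of ordered lags
  $t_b - t_a$ in 1-ms half-open bins over ±100 ms; pairs are eligible
  with > 100 spikes each. Each of 1000 surrogates adds independent
  N(0, 50 ms) offsets to every spike of *both* trains (a symmetric null —
  the published description does not say one or both; a one-train mode is
  available), re-sorts and recounts. Per-bin 99% bounds are empirical
  [0.5%, 99.5%] quantiles with linear interpolation. Significance: any
  bin with |lag| ∈ [1.5, 30] ms strictly above the upper bound. Whether a
  significant peak falls within ±25 ms of the origin is reported as a
  separate descriptive flag, not as the criterion: the interval criterion
  is the operational rule, the ±25 ms phrasing a description of where
  peaks were found.
* **Dithered coincidences.** A coincidence is an ordered cross pair in
  the same event with $|t_b - t_a| \le 2.5$ ms (5-ms total window),
  assigned to the 10-ms peri-event bin of the earlier spike — this makes
  the count a pure pair count with an exhaustive $O(nm)$ oracle, used
  verbatim in the tests (a greedy at-most-one-partner matching is
  available via `rule = "greedy"`). Surrogates dither every latency by U(−5, +5) ms, clipping
  into the raster window minus a tiny epsilon so counts are preserved;
  the per-bin threshold is the empirical 99.9% quantile of 1000 surrogate
  counts, and the overall flag fires when an exceeding bin lies in the
  pre-ID or ID window.

Numerical notes. With 1000 surrogates the 99.9% quantile is effectively
an extreme order statistic; interpolated quantiles of integer counts need
not be integers. On *discrete* counts both bands are conservative: ties
at the quantile count as "inside", so the jitter band's coverage sits
slightly above 99% (measured ≈ 99.3% on independent Poisson pairs) and
the dither exceedance below 0.1% — markedly so at low per-bin counts.
This is a property of empirical bands on counts, not an implementation
artefact; the calibration tests therefore compute their binomial error
over the number of independent pair datasets (bins within a pair share
both trains and all surrogates and are strongly dependent), and the
dither check asserts the exceedance does not *exceed* its nominal level
beyond that error.

A caution for interpretation, visible in the worked example: units that
co-modulate sharply around events (e.g. both tripling their rate in a
100-ms window) are correlated at exactly the timescale a 50-ms jitter
only partly destroys, so the correlogram test fires on such pairs without
any millisecond coupling. The dither test, whose null preserves structure
above the 5-ms scale, is the sharper instrument for millisecond synchrony.

## The synthetic-data generator

`gen_lfp()` synthesises $1/f^\alpha$ Gaussian noise spectrally
(α = 1 by default — a realistic spectral slope that actually stresses the
per-frequency Z-normalisation, unlike white noise), normalised to robust
SD 1. Discharges are a difference-of-Gaussians sharp component (FWHM
`id_sharp_width_ms` = 60 ms, admissible 20–100) plus an opposite-polarity
slow half-wave (350 ms, admissible 200–500), scaled to peak at
`id_amp_snr` = 8 robust SDs, placed at renewal times (exponential gaps
plus a 2-s refractory) targeting 0.07 Hz; a rate so high the refractory
cannot be honoured is an error. An optional pre-ID burst adds a
Hann-enveloped sinusoid (default 90 Hz) in the −300..−50 ms window whose
band power is `gain` times the background band power; at the default
gain 10 the averaged peri-event Z peak lands near 6, the scale such
pre-discharge gamma bursts reach in human microelectrode recordings.

`gen_units()` draws inhomogeneous Poisson trains by thinning: baseline
rates U(2, 7) Hz, multiplied by the unit's class gain inside its class
window around every true event. Gating is piecewise-constant by design —
it makes every per-window rate analytically known, so parameter-recovery
tests have exact targets; the price is the sharp co-modulation discussed
above. Default composition (12 ID-increase ×3.5, 16 post-decrease ×0.3,
5 pre-increase ×2.4, 7 pre-decrease ×0.45 in 40 units) mirrors the
modulated-unit proportions and rate scales the analysis is designed to
resolve. A 1.5-ms absolute refractory is enforced by deletion, so every
generated train passes the ISI filter by construction; the ~0.5% rate
deficit this causes is far inside the 3-SE tolerances of the moment
tests. Correlated pairs copy a shared selection of a mother train into
both units with independent N(0, jitter) offsets, giving a central
correlogram peak of width ≈ √2 × jitter.

All randomness flows from `master_seed` through named substreams
(`derive_seed()`), so the LFP, the units and any pair can be regenerated
independently and `gen_dataset()` is byte-reproducible.

**What passing tests show — and don't.** Recovery on this generator
demonstrates that the estimators are unbiased and calibrated under their
own assumptions (Poisson spiking, multiplicative gating, Gaussian 1/f
background, stereotyped template). Real recordings add bursting and
refractory structure beyond Poisson, waveform variability across
discharges, non-stationary background, and unit co-modulation that is
smooth rather than gated; none of these is emulated, and percentages
obtained on real data depend on them. The synthetic results validate the
machinery, not the clinical numbers.

## Problem sizes and reproducibility

The shipped tests run the oracle comparisons on hundreds of random pairs
(up to 10³ spikes), the surrogate calibrations on 200 independent Poisson
pair datasets with the full 1000 surrogates each, and parameter recovery
on a 40-unit dataset with ~150 discharges (≈ 37 minutes of simulated
recording) — sizes chosen so the whole suite exercises every default
parameter at its production value while remaining desk-scale. The
acceptance script (`scripts/acceptance.R`) recomputes the surrogate
calibration from scratch under a caller-supplied seed. Two runs of any
stage with the same configuration and seed produce byte-identical
outputs; this, too, is under test.

## Known limitations

* The detector's thresholds are defaults for SNR-8 discharges on a
  1/f background; very low-SNR or highly non-stationary recordings need
  re-tuning (`detector_params()` exposes everything).
* The pre-ID significance rule is one defensible choice among several;
  the per-unit statistic and p-value are reported so alternatives can be
  applied downstream.
* The jitter correlogram test inherits the usual sensitivity to sharp
  rate co-modulation (see above).
* EDF support covers the standard 16-bit physical-scaling layout (the
  package's writer emits single-channel files; the reader handles
  multi-channel records); EDF+ annotations and vendor-native binary
  formats are out of scope.
* No multiple-testing correction is applied across pairs by default —
  the per-pair levels are reported, and the pipeline states them — since
  the canonical analysis applies none either.
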