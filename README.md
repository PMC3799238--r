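# iedflow

Peri-event analysis of **interictal epileptiform discharges (IDs)** in
human microelectrode recordings: how single neurons and the local field
potential (LFP) behave in the seconds around each discharge.

The package is aimed at electrophysiologists working with sorted
single-unit spike trains and LFP from depth microwires (epilepsy
monitoring, hippocampus/entorhinal cortex). It provides a tested,
reproducible implementation of the full analysis chain:

1. **ID detection and alignment** — a threshold detector on the detrended
   LFP: a candidate is a contiguous excursion beyond
   $k_a \hat\sigma$ (robust SD, $\hat\sigma = 1.4826\,\mathrm{MAD}$) whose
   lagged-difference slope exceeds $k_s \hat\sigma_\Delta$ and whose
   crossing width lies in 20–100 ms; events are aligned on the sharpest
   peak.
2. **Peri-event unit analysis** — ISI-violation quality filter (< 0.5%
   intervals under 1 ms), Gaussian-kernel instantaneous rate
   ($\sigma$ = 20 ms, unit area per spike), rasters and 10-ms PSTHs over
   ±1 s, and modulation classification over the canonical windows
   (baseline −600..−300, pre-ID −300..−50, ID −50..50, post-ID 50..400 ms):
   ID *increase* iff rate ratio ≥ 2, post-ID *decrease* iff ratio ≤ 0.5,
   pre-ID change by a per-unit paired t-test across events; group-level
   one-tailed t-tests on per-unit differences (df = n − 1).
3. **Time–frequency analysis** — complex Morlet transform
   $\Psi_{\tau,f}(u) = f\,e^{j2\pi f(u-\tau)}\,e^{-(u-\tau)^2/2\sigma^2}$
   with $n_{co} = 6 f \sigma = 5$, power $|W|^2$ Z-scored per frequency
   against the pooled pre-event baseline; $|Z| > 3.09$ marks $P < 0.001$;
   peak pre-ID score in the 40–120 Hz band; Lilliefors normality check of
   the coefficients.
4. **Spike synchrony** — two surrogate tests per unit pair:
   cross-correlograms (1-ms bins, ±100 ms) against a 99% band from 1000
   surrogates with N(0, 50 ms) spike jitter, significant if any bin in
   |lag| ∈ [1.5, 30] ms exceeds the band; and 5-ms coincidence counts per
   10-ms peri-event bin against the 99.9% threshold from 1000 surrogates
   with U(−5, +5) ms dither.
5. **Synthetic data with ground truth** — 1/f LFP with embedded discharge
   templates (sharp biphasic component + slow wave, optional pre-ID gamma
   burst) and inhomogeneous-Poisson units with known modulation classes
   and injected correlated pairs, so every stage can be validated by
   parameter recovery.

## Worked example

```r
library(iedflow)

cfg <- run_config(
  sim = sim_config(duration_s = 600,
                   units = sim_units_spec(n = 20,
                     classes = rep(c("id_increase", "post_decrease", "none"),
                                   times = c(6, 8, 6)))),
  n_surrogates = 1000, max_pairs = 6, run_spectral = FALSE, seed = 42)
rep <- run_pipeline(cfg)
summary(rep)
```

```
<run_report> iedflow 0.1.0, seed 42
  39 events (0.065 Hz), 20 units after ISI filter
  modulation class proportions:
    id_increase     6/20 = 0.30  [0.12, 0.54]
    post_decrease   7/20 = 0.35  [0.15, 0.59]
    pre_increase    1/20 = 0.05  [0.00, 0.25]
    pre_decrease    0/20 = 0.00  [0.00, 0.17]
  synchrony: 6 pairs, 17% CCG-significant, 0% coincidence-significant
  group ID vs baseline (right tail): T(19) = 2.67, p = 0.00761
  group post-ID vs baseline (left tail): T(19) = -3.08, p = 0.00308
```

Reading this: 39 discharges were detected in 10 minutes of simulated LFP
(0.065 Hz, the generator's target is 0.07 Hz). The simulation contained 6
ID-activated, 8 post-ID-suppressed and 6 unmodulated units; the classifier
reports 6/20 = 0.30 `id_increase` and 7/20 = 0.35 `post_decrease` (each
with its exact binomial 95% interval), and the group tests show the
expected directions. One of six
unit pairs trips the correlogram test — units that co-modulate around each
discharge are correlated at the ~100-ms timescale, which a 50-ms jitter
null only partly absorbs (see the methods vignette).

Each stage is equally usable on its own (`detect_ids()`,
`classify_modulation()`, `event_tf_zscore()`, `analyze_pair()`, ...), on
data read from CSV/EDF via `read_lfp()`, `read_spike_trains()`,
`read_events()`. A small command-line front-end lives at
`inst/scripts/iedflow.R`.

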