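// Inner loops for surrogate-based synchrony tests: cross-correlogram
// counting, normal-jitter surrogates, peri-event coincidence counting and
// uniform-dither surrogates. All randomness goes through R's RNG so results
// are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// counts of lags t_b - t_a in half-open bins covering [-max_lag, max_lag)
static void ccg_fill(const double* a, int na, const double* b, int nb,
                     double max_lag, double bin_w, int nbins, int* counts) {
  int lo = 0;
  for (int i = 0; i < na; ++i) {
    const double t = a[i];
    while (lo < nb && b[lo] < t - max_lag) ++lo;
    for (int j = lo; j < nb; ++j) {
      const double lag = b[j] - t;
      if (lag >= max_lag) break;
      const int k = (int)std::floor((lag + max_lag) / bin_w);
      if (k >= 0 && k < nbins) ++counts[k];
    }
  }
}

// [[Rcpp::export(name = ".ccg_count_cpp")]]
IntegerVector ccg_count_cpp(NumericVector a, NumericVector b,
                            double max_lag, double bin_w) {
  const int nbins = (int)std::lround(2.0 * max_lag / bin_w);
  IntegerVector counts(nbins);
  ccg_fill(a.begin(), a.size(), b.begin(), b.size(), max_lag, bin_w, nbins,
           counts.begin());
  return counts;
}

// n_surr jittered correlograms; every spike of both trains receives an
// independent N(0, sd) offset per surrogate
// [[Rcpp::export(name = ".ccg_jitter_surr_cpp")]]
IntegerMatrix ccg_jitter_surr_cpp(NumericVector a, NumericVector b,
                                  double max_lag, double bin_w, double sd,
                                  int n_surr) {
  const int nbins = (int)std::lround(2.0 * max_lag / bin_w);
  const int na = a.size(), nb = b.size();
  IntegerMatrix out(nbins, n_surr);
  std::vector<double> ja(na), jb(nb);
  RNGScope scope;
  for (int s = 0; s < n_surr; ++s) {
    for (int i = 0; i < na; ++i) ja[i] = a[i] + (sd > 0 ? R::rnorm(0.0, sd) : 0.0);
    for (int i = 0; i < nb; ++i) jb[i] = b[i] + (sd > 0 ? R::rnorm(0.0, sd) : 0.0);
    std::sort(ja.begin(), ja.end());
    std::sort(jb.begin(), jb.end());
    ccg_fill(ja.data(), na, jb.data(), nb, max_lag, bin_w, nbins,
             &out(0, s));
  }
  return out;
}

// coincidences: cross pairs within one event with |lb - la| <= half_win,
// binned at the earlier spike's latency; latencies sorted within events.
// rule 0: every ordered cross pair counts (pure pair count).
// rule 1: greedy matching, each spike in at most one coincidence.
static void coinc_fill(const double* la, const int* ea, int na,
                       const double* lb, const int* eb, int nb,
                       double half_win, double bin_w, double t_min,
                       int nbins, int rule, int* counts) {
  if (rule == 0) {
    int jlo = 0;
    for (int i = 0; i < na; ++i) {
      const int ev = ea[i];
      const double t = la[i];
      while (jlo < nb && (eb[jlo] < ev || (eb[jlo] == ev && lb[jlo] < t - half_win)))
        ++jlo;
      for (int j = jlo; j < nb; ++j) {
        if (eb[j] != ev || lb[j] > t + half_win) break;
        const double earlier = std::min(t, lb[j]);
        const int k = (int)std::floor((earlier - t_min) / bin_w);
        if (k >= 0 && k < nbins) ++counts[k];
      }
    }
  } else {
    int i = 0, j = 0;
    while (i < na && j < nb) {
      if (ea[i] < eb[j]) { ++i; continue; }
      if (eb[j] < ea[i]) { ++j; continue; }
      const double d = lb[j] - la[i];
      if (d < -half_win) { ++j; continue; }
      if (d > half_win) { ++i; continue; }
      const double earlier = std::min(la[i], lb[j]);
      const int k = (int)std::floor((earlier - t_min) / bin_w);
      if (k >= 0 && k < nbins) ++counts[k];
      ++i; ++j;
    }
  }
}

// [[Rcpp::export(name = ".coincidence_count_cpp")]]
IntegerVector coincidence_count_cpp(NumericVector la, IntegerVector ea,
                                    NumericVector lb, IntegerVector eb,
                                    double half_win, double bin_w,
                                    double t_min, double t_max, int rule) {
  const int nbins = (int)std::lround((t_max - t_min) / bin_w);
  IntegerVector counts(nbins);
  coinc_fill(la.begin(), ea.begin(), la.size(), lb.begin(), eb.begin(),
             lb.size(), half_win, bin_w, t_min, nbins, rule, counts.begin());
  return counts;
}

struct EvLat { int ev; double lat; };
static bool evlat_less(const EvLat& x, const EvLat& y) {
  return x.ev < y.ev || (x.ev == y.ev && x.lat < y.lat);
}

static void dither_sort(const double* lat, const int* ev, int n,
                        double halfwidth, double t_min, double t_max,
                        std::vector<EvLat>& out) {
  const double eps = 1e-6;
  for (int i = 0; i < n; ++i) {
    double t = lat[i] + R::runif(-halfwidth, halfwidth);
    // clip to the raster window minus a uniform epsilon, preserving counts
    if (t < t_min) t = t_min + eps * R::unif_rand();
    if (t >= t_max) t = t_max - eps * (1.0 + R::unif_rand());
    out[i].ev = ev[i];
    out[i].lat = t;
  }
  std::sort(out.begin(), out.end(), evlat_less);
}

// [[Rcpp::export(name = ".coincidence_dither_surr_cpp")]]
IntegerMatrix coincidence_dither_surr_cpp(NumericVector la, IntegerVector ea,
                                          NumericVector lb, IntegerVector eb,
                                          double half_win, double bin_w,
                                          double t_min, double t_max,
                                          double halfwidth, int n_surr,
                                          int rule) {
  const int nbins = (int)std::lround((t_max - t_min) / bin_w);
  const int na = la.size(), nb = lb.size();
  IntegerMatrix out(nbins, n_surr);
  std::vector<EvLat> da(na), db(nb);
  std::vector<double> lat_a(na), lat_b(nb);
  std::vector<int> ev_a(na), ev_b(nb);
  RNGScope scope;
  for (int s = 0; s < n_surr; ++s) {
    dither_sort(la.begin(), ea.begin(), na, halfwidth, t_min, t_max, da);
    dither_sort(lb.begin(), eb.begin(), nb, halfwidth, t_min, t_max, db);
    for (int i = 0; i < na; ++i) { lat_a[i] = da[i].lat; ev_a[i] = da[i].ev; }
    for (int i = 0; i < nb; ++i) { lat_b[i] = db[i].lat; ev_b[i] = db[i].ev; }
    coinc_fill(lat_a.data(), ev_a.data(), na, lat_b.data(), ev_b.data(), nb,
               half_win, bin_w, t_min, nbins, rule, &out(0, s));
  }
  return out;
}
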