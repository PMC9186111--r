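#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sequential dithering kernels. Both process the spikes of one train left to
// right against the already-dithered predecessor, so they are inherently
// serial; the loops live here to keep large trains fast. All randomness
// comes from R's RNG stream (reproducible under set.seed()).

// Uniform dithering with dead-time: spike i is placed uniformly in
// [max(t0, s_i - dither, prev' + dead), min(t1, s_i + dither, s_{i+1} - dead)];
// an empty window leaves the spike in place (counted in n_stuck).

// [[Rcpp::export]]
List udd_dither_cpp(NumericVector times, double t0, double t1,
                    double dither, double dead) {
  const int n = times.size();
  NumericVector out(n);
  int stuck = 0;
  double prev = R_NegInf;
  for (int i = 0; i < n; ++i) {
    double lo = std::max(t0, std::max(times[i] - dither, prev + dead));
    double hi = std::min(t1, times[i] + dither);
    if (i + 1 < n) hi = std::min(hi, times[i + 1] - dead);
    if (hi <= lo) {
      out[i] = times[i];
      ++stuck;
    } else {
      out[i] = R::runif(lo, hi);
    }
    prev = out[i];
  }
  return List::create(_["times"] = out, _["n_stuck"] = stuck);
}

// Joint-ISI dithering along the anti-diagonal of the (smoothed, possibly
// dead-time-cut) joint-ISI matrix J, discretized at bin width h. The new
// preceding interval tau_new is sampled by inverse CDF from
// J(tau_new, total - tau_new) weighted by the admissible overlap of each
// histogram bin with (lo, hi); indices beyond the histogram support are
// clamped to the last bin.

// [[Rcpp::export]]
List jisi_dither_cpp(NumericVector times, NumericMatrix J, double h,
                     double cutoff, double dither) {
  const int n = times.size();
  const int nb = J.nrow();
  NumericVector out = clone(times);
  int stuck = 0;
  std::vector<double> w(nb);
  for (int i = 1; i < n - 1; ++i) {
    const double tau = times[i] - out[i - 1];
    const double taup = times[i + 1] - times[i];
    const double total = tau + taup;
    const double lo = std::max(cutoff, tau - dither);
    const double hi = std::min(total - cutoff, tau + dither);
    if (hi <= lo) { ++stuck; continue; }
    int k_lo = std::max(1, (int)std::floor(lo / h) + 1);
    int k_hi = std::min(nb, (int)std::floor(hi / h) + 1);
    if (k_hi < k_lo) { ++stuck; continue; }
    double tot = 0.0;
    for (int k = k_lo; k <= k_hi; ++k) {
      int kp = (int)std::floor((total - (k - 0.5) * h) / h) + 1;
      kp = std::min(std::max(kp, 1), nb);
      const double seg_lo = std::max(lo, (k - 1) * h);
      const double seg_hi = std::min(hi, k * h);
      const double wk = J(k - 1, kp - 1) * std::max(seg_hi - seg_lo, 0.0);
      w[k - k_lo] = wk;
      tot += wk;
    }
    if (!(tot > 0.0) || !R_finite(tot)) { ++stuck; continue; }
    double u = R::unif_rand() * tot;
    int k = k_hi;
    for (int j = k_lo; j <= k_hi; ++j) {
      u -= w[j - k_lo];
      if (u <= 0) { k = j; break; }
    }
    const double a = std::max(lo, (k - 1) * h);
    const double b = std::min(hi, (double)k * h);
    out[i] = out[i - 1] + R::runif(a, b);
  }
  return List::create(_["times"] = out, _["n_stuck"] = stuck);
}
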