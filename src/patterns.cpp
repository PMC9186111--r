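#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Exhaustive support counting of size-3 spatiotemporal patterns.
//
// A transaction is the content of a w-bin context window sliding over every
// start bin where the window fits: the items are (unit, lag) pairs with
// lag in 0..w-1, encoded as item = lag * U + unit so that lag-0 items sort
// first. A size-3 pattern is a set of three distinct items containing at
// least one lag-0 item; its support is the number of window start positions
// (pooled over trials) whose transaction contains all three items. Each
// qualifying 3-subset is enumerated once via its smallest item, which is a
// lag-0 item by the encoding, so every spatiotemporal occurrence is counted
// exactly once, anchored at the window start of its lag-0 item.
//
// Counting is organised per anchor unit: the U*w x U*w pair-count slab of
// one anchor fits the cache, which keeps the scattered increments fast.

namespace {

struct Transactions {
  std::vector<int> items;   // concatenated, sorted within transaction
  std::vector<int> offset;  // start of each transaction in `items`
  std::vector<int> n_lag0;  // number of lag-0 items per transaction
  int U, w, M, n_trans;
};

Transactions build_transactions(List occs, int w) {
  if (occs.size() == 0) stop("no occupancy matrices supplied");
  IntegerMatrix first = occs[0];
  Transactions tr;
  tr.U = first.nrow();
  tr.w = w;
  tr.M = tr.U * w;
  tr.n_trans = 0;
  for (int trial = 0; trial < occs.size(); ++trial) {
    IntegerMatrix occ = occs[trial];
    if (occ.nrow() != tr.U) stop("all trials must have the same units");
    const int B = occ.ncol();
    if (w < 1 || w > B) stop("window width must be in 1..n_bins");
    const int n_starts = B - w + 1;
    for (int t = 0; t < n_starts; ++t) {
      tr.offset.push_back((int)tr.items.size());
      int nl0 = 0;
      for (int lag = 0; lag < w; ++lag) {
        const int col = t + lag;
        for (int u = 0; u < tr.U; ++u) {
          if (occ(u, col) != 0) {
            tr.items.push_back(lag * tr.U + u);
            if (lag == 0) ++nl0;
          }
        }
      }
      tr.n_lag0.push_back(nl0);
      ++tr.n_trans;
    }
  }
  tr.offset.push_back((int)tr.items.size());
  if (tr.n_trans > 60000)
    stop("too many window positions for 16-bit support counters");
  return tr;
}

// fill the pair-count slab of one anchor unit; returns false if the anchor
// never fires
bool fill_slab(const Transactions &tr, int a, std::vector<uint16_t> &slab) {
  std::fill(slab.begin(), slab.end(), 0);
  bool any = false;
  const int M = tr.M;
  for (int t = 0; t < tr.n_trans; ++t) {
    const int lo = tr.offset[t], hi = tr.offset[t + 1];
    int p = -1;
    for (int q = lo; q < lo + tr.n_lag0[t]; ++q) {
      if (tr.items[q] == a) { p = q; break; }
    }
    if (p < 0) continue;
    any = true;
    for (int i = p + 1; i < hi; ++i) {
      uint16_t *row = slab.data() + (size_t)tr.items[i] * M;
      for (int j = i + 1; j < hi; ++j) ++row[tr.items[j]];
    }
  }
  return any;
}

} // namespace

// Returns an integer matrix H with w rows (durations 0..w-1) and one column
// per support value c = 1, 2, ...: H(d, c-1) is the number of distinct
// size-3 patterns with duration d (maximal lag) and pooled support exactly c.
// occs: list of integer 0/1 occupancy matrices (units x bins), one per trial.

// [[Rcpp::export]]
IntegerMatrix count_triplet_supports(List occs, int w) {
  Transactions tr = build_transactions(occs, w);
  const int U = tr.U, M = tr.M;
  std::vector<uint16_t> slab((size_t)M * M);
  IntegerMatrix H(w, tr.n_trans > 0 ? tr.n_trans : 1);
  for (int a = 0; a < U; ++a) {
    if (!fill_slab(tr, a, slab)) continue;
    for (int i = a + 1; i < M; ++i) {
      const int lag_i = i / U;
      const uint16_t *row = slab.data() + (size_t)i * M;
      for (int j = i + 1; j < M; ++j) {
        const int c = row[j];
        if (c > 0) H(std::max(lag_i, j / U), c - 1) += 1;
      }
    }
  }
  return H;
}

// Enumerate all size-3 patterns (with a lag-0 item) whose pooled support
// reaches min_support. Returns a matrix with columns: unit1, lag1, unit2,
// lag2, unit3, lag3, support (units 0-based, lags in bins).

// [[Rcpp::export]]
IntegerMatrix triplets_above(List occs, int w, int min_support) {
  Transactions tr = build_transactions(occs, w);
  const int U = tr.U, M = tr.M;
  std::vector<uint16_t> slab((size_t)M * M);
  std::vector<int> rows;
  for (int a = 0; a < U; ++a) {
    if (!fill_slab(tr, a, slab)) continue;
    for (int i = a + 1; i < M; ++i) {
      const uint16_t *row = slab.data() + (size_t)i * M;
      for (int j = i + 1; j < M; ++j) {
        const int c = row[j];
        if (c >= min_support) {
          rows.push_back(a); rows.push_back(i); rows.push_back(j);
          rows.push_back(c);
        }
      }
    }
  }
  const int np = (int)(rows.size() / 4);
  IntegerMatrix out(np, 7);
  for (int r = 0; r < np; ++r) {
    const int i = rows[4 * r + 1], j = rows[4 * r + 2];
    out(r, 0) = rows[4 * r]; out(r, 1) = 0;
    out(r, 2) = i % U;       out(r, 3) = i / U;
    out(r, 4) = j % U;       out(r, 5) = j / U;
    out(r, 6) = rows[4 * r + 3];
  }
  colnames(out) = CharacterVector::create("unit1", "lag1", "unit2", "lag2",
                                          "unit3", "lag3", "support");
  return out;
}

// Pooled support of a single explicit pattern: the number of window start
// positions (over all trials) whose transaction contains every (unit, lag)
// item. units are 0-based row indices, lags in 0..w-1.

// [[Rcpp::export]]
int count_pattern_support(List occs, IntegerVector units,
                          IntegerVector lags, int w) {
  const int k = units.size();
  int c = 0;
  for (int trial = 0; trial < occs.size(); ++trial) {
    IntegerMatrix occ = occs[trial];
    const int n_starts = occ.ncol() - w + 1;
    for (int t = 0; t < n_starts; ++t) {
      bool ok = true;
      for (int m = 0; m < k; ++m) {
        if (occ(units[m], t + lags[m]) == 0) { ok = false; break; }
      }
      if (ok) ++c;
    }
  }
  return c;
}
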