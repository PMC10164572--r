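#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <climits>

using namespace Rcpp;

// Semiglobal unit-cost edit distance: alignments are anchored at position 0
// of both sequences, gaps at the ends of either sequence are free. The
// distance is the minimum over the last row and last column of the standard
// edit-distance DP. 'N' is treated as matching nothing (conservative for
// ambiguity codes).
//
// band >= 0 restricts the DP to |i - j| <= band. Any alignment of cost d
// deviates from the diagonal by at most d cells, so the banded value is
// exact whenever the true distance is < band; otherwise the function
// returns a value > band which the caller only uses to conclude "beyond
// the radius".
//
// limit >= 0 allows early termination: once every cell of a row exceeds
// limit the true distance (and the boundary minimum) must exceed limit,
// and limit + 1 is returned.

static const int BIG = INT_MAX / 4;

static inline bool base_match(char x, char y) {
  return x == y && x != 'N';
}

static int sg_dist_one(const std::string& a, const std::string& b,
                       int band, int limit) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  int best = BIG;  // min over last column (j == n) and, later, last row
  for (int j = 0; j <= n; ++j)
    prev[j] = (band >= 0 && j > band) ? BIG : j;
  if (m == 0) return 0;
  if (band < 0) band = std::max(m, n);  // effectively unbanded
  for (int i = 1; i <= m; ++i) {
    int lo = std::max(0, i - band), hi = std::min(n, i + band);
    if (lo > hi) break;  // band has slid past b entirely
    int rowmin = BIG;
    if (lo > 0) cur[lo - 1] = BIG;
    for (int j = lo; j <= hi; ++j) {
      int v;
      if (j == 0) {
        v = i;
      } else {
        int diag = prev[j - 1] == BIG ? BIG
                   : prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? 0 : 1);
        int up   = prev[j] == BIG ? BIG : prev[j] + 1;
        int left = cur[j - 1] == BIG ? BIG : cur[j - 1] + 1;
        v = std::min(diag, std::min(up, left));
      }
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (hi < n) cur[hi + 1] = BIG;  // guard for next row's 'up'
    if (hi == n && cur[n] < best) best = cur[n];  // last column, trailing gap in a free
    if (limit >= 0 && rowmin > limit && best > limit) return limit + 1;
    std::swap(prev, cur);
  }
  // last row: trailing gap in b free
  int lo = std::max(0, m - band), hi = std::min(n, m + band);
  for (int j = lo; j <= hi; ++j)
    if (prev[j] < best) best = prev[j];
  return best;
}

// [[Rcpp::export(name = ".sg_dist")]]
IntegerVector sg_dist(CharacterVector a, CharacterVector b,
                      int band = -1, int limit = -1) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    std::string sa = as<std::string>(a[i]), sb = as<std::string>(b[i]);
    if (sa.empty() || sb.empty()) stop("sequences must be non-empty");
    out[i] = sg_dist_one(sa, sb, band, limit);
  }
  return out;
}

static inline double sim_from_dist(int d, int la, int lb) {
  int shorter = std::min(la, lb);
  double s = 1.0 - (double)d / (double)shorter;
  return s < 0.0 ? 0.0 : s;
}

// element-wise exact similarity (full DP)
// [[Rcpp::export(name = ".sg_similarity")]]
NumericVector sg_similarity(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    std::string sa = as<std::string>(a[i]), sb = as<std::string>(b[i]);
    if (sa.empty() || sb.empty()) stop("sequences must be non-empty");
    int d = sg_dist_one(sa, sb, -1, -1);
    out[i] = sim_from_dist(d, (int)sa.size(), (int)sb.size());
  }
  return out;
}

// maximum edit distance compatible with similarity >= threshold for a pair
// whose shorter length is 'shorter' (small epsilon absorbs FP noise in
// (1 - threshold) * shorter when it is an exact integer)
static inline int max_dist_for(double threshold, int shorter) {
  return (int)std::floor((1.0 - threshold + 1e-9) * (double)shorter);
}

// Similarity of every pool sequence to every representative, reported only
// where it reaches the threshold; NA elsewhere. Banded DP with band one
// beyond the admissible distance, so reported values are exact.
// [[Rcpp::export(name = ".sim_to_reps")]]
NumericMatrix sim_to_reps(CharacterVector pool, CharacterVector reps,
                          double threshold) {
  const int np = (int)pool.size(), nr = (int)reps.size();
  NumericMatrix out(np, nr);
  std::vector<std::string> rs(nr);
  for (int k = 0; k < nr; ++k) rs[k] = as<std::string>(reps[k]);
  for (int i = 0; i < np; ++i) {
    std::string p = as<std::string>(pool[i]);
    if (p.empty()) stop("sequences must be non-empty");
    for (int k = 0; k < nr; ++k) {
      if (rs[k].empty()) stop("sequences must be non-empty");
      int shorter = std::min((int)p.size(), (int)rs[k].size());
      int maxd = max_dist_for(threshold, shorter);
      int d = sg_dist_one(p, rs[k], maxd + 1, maxd);
      out(i, k) = (d <= maxd) ? sim_from_dist(d, (int)p.size(), (int)rs[k].size())
                              : NA_REAL;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Greedy first-match clustering of sequences already sorted in processing
// order: each sequence joins the FIRST existing cluster whose representative
// (the cluster's seeding sequence) it matches at >= threshold, else it seeds
// a new cluster. Returns 1-based cluster index per sequence, plus the
// similarity to the representative.
// [[Rcpp::export(name = ".greedy_first_match")]]
List greedy_first_match(CharacterVector seqs, double threshold) {
  const int n = (int)seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    if (ss[i].empty()) stop("sequences must be non-empty");
  }
  IntegerVector cl(n);
  NumericVector sim(n);
  std::vector<int> rep_idx;  // index of each cluster's representative
  for (int i = 0; i < n; ++i) {
    int assigned = 0;
    double s_as = 1.0;
    for (size_t k = 0; k < rep_idx.size(); ++k) {
      const std::string& r = ss[rep_idx[k]];
      int shorter = std::min((int)ss[i].size(), (int)r.size());
      int maxd = max_dist_for(threshold, shorter);
      int d = sg_dist_one(ss[i], r, maxd + 1, maxd);
      if (d <= maxd) {
        assigned = (int)k + 1;
        s_as = sim_from_dist(d, (int)ss[i].size(), (int)r.size());
        break;
      }
    }
    if (assigned == 0) {
      rep_idx.push_back(i);
      cl[i] = (int)rep_idx.size();
      sim[i] = 1.0;
    } else {
      cl[i] = assigned;
      sim[i] = s_as;
    }
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerVector reps(rep_idx.size());
  for (size_t k = 0; k < rep_idx.size(); ++k) reps[k] = rep_idx[k] + 1;
  return List::create(_["cluster"] = cl, _["similarity"] = sim,
                      _["rep_index"] = reps);
}
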