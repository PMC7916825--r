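#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Weighted Kolmogorov-Smirnov running-sum enrichment scores.
//
// metric:  features x n_cols matrix of ranking-metric values (column 0 is
//          typically the observed metric, the rest label permutations).
// set_idx: list of integer vectors, 0-based row indices of each set's
//          member features.
// weight:  exponent on |metric| for the hit increments (1 in the original
//          formulation).
//
// Returns a sets x n_cols matrix of enrichment scores. For each column the
// features are ranked by decreasing metric (ties broken by row index); the
// running sum gains |metric|^weight / NR at member positions and loses
// 1/(N-K) elsewhere; the ES is the signed deviation of largest magnitude.
// Peaks can only occur just after a hit, troughs just before one, so only
// those 2K candidate points are evaluated per set.
// Signal-to-noise ranking metric under a batch of case assignments.
//
// vals:     features x samples intensity matrix.
// case_ind: samples x n_cols 0/1 indicator of case membership (column 0 is
//           typically the observed assignment).
//
// Each group's standard deviation is floored at 0.2 * max(|group mean|, 1)
// so that near-constant features cannot dominate the ranking.
// [[Rcpp::export]]
NumericMatrix s2n_metric_matrix(const NumericMatrix& vals,
                                const NumericMatrix& case_ind) {
  const int n_feat = vals.nrow();
  const int n_samp = vals.ncol();
  const int n_cols = case_ind.ncol();
  NumericMatrix metric(n_feat, n_cols);
  for (int c = 0; c < n_cols; ++c) {
    int n1 = 0;
    for (int s = 0; s < n_samp; ++s) n1 += (case_ind(s, c) > 0);
    const int n2 = n_samp - n1;
    for (int f = 0; f < n_feat; ++f) {
      double s1 = 0, s2 = 0, q1 = 0, q2 = 0;
      for (int s = 0; s < n_samp; ++s) {
        const double v = vals(f, s);
        if (case_ind(s, c) > 0) { s1 += v; q1 += v * v; }
        else { s2 += v; q2 += v * v; }
      }
      const double m1 = s1 / n1, m2 = s2 / n2;
      double v1 = (q1 - n1 * m1 * m1) / (n1 - 1);
      double v2 = (q2 - n2 * m2 * m2) / (n2 - 1);
      double sd1 = v1 > 0 ? std::sqrt(v1) : 0.0;
      double sd2 = v2 > 0 ? std::sqrt(v2) : 0.0;
      const double f1 = 0.2 * std::max(std::fabs(m1), 1.0);
      const double f2 = 0.2 * std::max(std::fabs(m2), 1.0);
      if (sd1 < f1) sd1 = f1;
      if (sd2 < f2) sd2 = f2;
      metric(f, c) = (m1 - m2) / (sd1 + sd2);
    }
  }
  return metric;
}

// [[Rcpp::export]]
NumericMatrix gsea_es_matrix(const NumericMatrix& metric, const List& set_idx,
                             const double weight) {
  const int n_feat = metric.nrow();
  const int n_cols = metric.ncol();
  const int n_sets = set_idx.size();
  NumericMatrix es(n_sets, n_cols);

  std::vector<int> ord(n_feat);
  std::vector<int> pos(n_feat);  // rank position (0-based) of each feature
  std::vector<double> absw(n_feat);

  for (int c = 0; c < n_cols; ++c) {
    const NumericMatrix::ConstColumn col = metric.column(c);
    std::iota(ord.begin(), ord.end(), 0);
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return col[a] > col[b]; });
    for (int r = 0; r < n_feat; ++r) pos[ord[r]] = r;
    for (int f = 0; f < n_feat; ++f) {
      double a = std::fabs(col[f]);
      absw[f] = (weight == 1.0) ? a : std::pow(a, weight);
    }
    for (int s = 0; s < n_sets; ++s) {
      const IntegerVector members = set_idx[s];
      const int K = members.size();
      if (K == 0 || K >= n_feat) { es(s, c) = NA_REAL; continue; }
      std::vector<std::pair<int, double> > hits(K);
      double nr = 0.0;
      for (int j = 0; j < K; ++j) {
        const int f = members[j];
        hits[j] = std::make_pair(pos[f], absw[f]);
        nr += absw[f];
      }
      std::sort(hits.begin(), hits.end());
      const double miss = 1.0 / (n_feat - K);
      const bool flat = (nr <= 0.0);  // all member metrics zero: equal weights
      if (flat) nr = K;
      double cum = 0.0, best = 0.0;
      for (int j = 0; j < K; ++j) {
        const int p = hits[j].first;
        // trough just before this hit
        const double before = cum / nr - (p - j) * miss;
        if (std::fabs(before) > std::fabs(best)) best = before;
        cum += flat ? 1.0 : hits[j].second;
        // peak just after this hit
        const double after = cum / nr - (p - j) * miss;
        if (std::fabs(after) > std::fabs(best)) best = after;
      }
      es(s, c) = best;
    }
  }
  return es;
}
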