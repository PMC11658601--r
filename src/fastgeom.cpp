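#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline double sqdist(const NumericMatrix &a, int i,
                            const NumericMatrix &b, int j) {
  double dx = a(i, 0) - b(j, 0);
  double dy = a(i, 1) - b(j, 1);
  double dz = a(i, 2) - b(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

// mean distance to the k nearest neighbours of each point (self excluded)
// [[Rcpp::export]]
NumericVector knn_avg_dist(NumericMatrix pts, int k) {
  int n = pts.nrow();
  NumericVector out(n);
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) d[j] = sqdist(pts, i, pts, j);
    d[i] = R_PosInf;
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::sqrt(d[j]);
    out[i] = s / k;
    d.assign(n, 0.0);
  }
  return out;
}

// greedy farthest point sampling; returns 1-based indices
// [[Rcpp::export]]
IntegerVector fps_cpp(NumericMatrix pts, int m, int start) {
  int n = pts.nrow();
  IntegerVector out(m);
  std::vector<double> mind(n, R_PosInf);
  int cur = start - 1;
  out[0] = cur + 1;
  for (int s = 1; s < m; ++s) {
    int best = 0;
    double bestd = -1.0;
    for (int j = 0; j < n; ++j) {
      double d = sqdist(pts, j, pts, cur);
      if (d < mind[j]) mind[j] = d;
      if (mind[j] > bestd) { bestd = mind[j]; best = j; }
    }
    cur = best;
    out[s] = cur + 1;
  }
  return out;
}

// up to k_max neighbours within radius of each center, nearest first;
// empty groups padded with the center's single nearest point and flagged.
// Returns list(idx = m x k_max 1-based, n_in = count within radius,
// padded = logical per center)
// [[Rcpp::export]]
List ball_query_cpp(NumericMatrix pts, NumericMatrix centers, double radius,
                    int k_max) {
  int n = pts.nrow(), m = centers.nrow();
  double r2 = radius * radius;
  IntegerMatrix idx(m, k_max);
  IntegerVector n_in(m);
  LogicalVector padded(m);
  std::vector<std::pair<double, int> > hits;
  for (int c = 0; c < m; ++c) {
    hits.clear();
    int nearest = 0;
    double nd = R_PosInf;
    for (int j = 0; j < n; ++j) {
      double d = sqdist(pts, j, centers, c);
      if (d <= r2) hits.push_back(std::make_pair(d, j));
      if (d < nd) { nd = d; nearest = j; }
    }
    std::sort(hits.begin(), hits.end());
    int take = std::min((int)hits.size(), k_max);
    if (take == 0) {
      padded[c] = true;
      for (int s = 0; s < k_max; ++s) idx(c, s) = nearest + 1;
      n_in[c] = 0;
    } else {
      for (int s = 0; s < take; ++s) idx(c, s) = hits[s].second + 1;
      for (int s = take; s < k_max; ++s) idx(c, s) = hits[0].second + 1;
      n_in[c] = take;
    }
  }
  return List::create(_["idx"] = idx, _["n_in"] = n_in, _["padded"] = padded);
}

// k nearest source points for each query point (brute force)
// [[Rcpp::export]]
List knn_query_cpp(NumericMatrix src, NumericMatrix q, int k) {
  int n = src.nrow(), m = q.nrow();
  if (k > n) k = n;
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<std::pair<double, int> > d(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j)
      d[j] = std::make_pair(sqdist(src, j, q, i), j);
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int s = 0; s < k; ++s) {
      idx(i, s) = d[s].second + 1;
      dist(i, s) = std::sqrt(d[s].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
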