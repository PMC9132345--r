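#include <Rcpp.h>
using namespace Rcpp;

// Victor-Purpura edit distance between two sorted spike trains: insert or
// delete costs 1 per spike, shifting a spike by dt costs q*|dt| (q in 1/s).
// Standard O(n*m) dynamic program.
static double vp_pair(const std::vector<double>& a,
                      const std::vector<double>& b, double q) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      double shift = prev[j - 1] + q * std::fabs(a[i - 1] - b[j - 1]);
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      cur[j] = std::min(shift, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double vp_distance_cpp(NumericVector a, NumericVector b, double q) {
  std::vector<double> va(a.begin(), a.end()), vb(b.begin(), b.end());
  return vp_pair(va, vb, q);
}

// Full pairwise distance matrix for a list of sorted spike trains.
// [[Rcpp::export]]
NumericMatrix vp_distance_matrix_cpp(List trains, double q) {
  const int n = trains.size();
  std::vector<std::vector<double>> tt(n);
  for (int i = 0; i < n; ++i) {
    NumericVector v = trains[i];
    tt[i] = std::vector<double>(v.begin(), v.end());
  }
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double val = vp_pair(tt[i], tt[j], q);
      d(i, j) = val;
      d(j, i) = val;
    }
  }
  return d;
}

// Coincidence count for the correlation index: number of ordered pairs of
// spikes from distinct trains with |dt| <= w/2.
// [[Rcpp::export]]
double coincidence_count_cpp(List trains, double w) {
  const int m = trains.size();
  double half = w / 2.0;
  double total = 0.0;
  for (int i = 0; i < m; ++i) {
    NumericVector a = trains[i];
    for (int j = i + 1; j < m; ++j) {
      NumericVector b = trains[j];
      int lo = 0, hi = 0;
      for (int k = 0; k < a.size(); ++k) {
        while (lo < b.size() && b[lo] < a[k] - half) ++lo;
        if (hi < lo) hi = lo;
        while (hi < b.size() && b[hi] <= a[k] + half) ++hi;
        total += (hi - lo);
      }
    }
  }
  return 2.0 * total;  // ordered train pairs
}

// All cross-trial spike-time differences (t_j - t_i, both orders) within
// +/- lag_max, for the shuffled autocorrelogram.
// [[Rcpp::export]]
NumericVector cross_differences_cpp(List trains, double lag_max) {
  const int m = trains.size();
  std::vector<double> out;
  for (int i = 0; i < m; ++i) {
    NumericVector a = trains[i];
    for (int j = 0; j < m; ++j) {
      if (i == j) continue;
      NumericVector b = trains[j];
      int lo = 0, hi = 0;
      for (int k = 0; k < a.size(); ++k) {
        while (lo < b.size() && b[lo] < a[k] - lag_max) ++lo;
        if (hi < lo) hi = lo;
        while (hi < b.size() && b[hi] <= a[k] + lag_max) ++hi;
        for (int l = lo; l < hi; ++l) out.push_back(b[l] - a[k]);
      }
    }
  }
  return wrap(out);
}
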