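#include <Rcpp.h>
using namespace Rcpp;

// Max convexity deficiency of the empirical cdf over the first m points of
// sorted data: builds the lower convex hull of (x_j, j/n) (lower step values,
// j = 0..m-1) and returns the largest amount by which the upper step value
// (j+1)/n sits above that hull. This is twice the sup-norm error of the best
// convex (left-limb) approximation to the ecdf on those points; atoms away
// from the mode and convexity violations both register here.
static double prefix_deficiency(const double* x, int m, int n,
                                std::vector<int>& hull) {
  hull.clear();
  if (m < 2) return 0.0;
  for (int j = 0; j < m; ++j) {
    while (hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      double cross = (x[b] - x[a]) * ((double)j - (double)a) -
                     (x[j] - x[a]) * ((double)b - (double)a);
      if (cross <= 0) hull.pop_back(); else break;
    }
    if (!hull.empty() && x[hull.back()] == x[j]) {
      // vertical tie: hull keeps the lowest y at this x
    } else {
      hull.push_back(j);
    }
  }
  double worst = 0.0;
  size_t h = 0;
  for (int j = 0; j < m; ++j) {
    while (h + 1 < hull.size() && x[hull[h + 1]] <= x[j]) ++h;
    int a = hull[h];
    double hy = (double)a / n;
    if (h + 1 < hull.size() && x[hull[h + 1]] > x[a]) {
      int b = hull[h + 1];
      hy += ((double)(b - a) / n) * (x[j] - x[a]) / (x[b] - x[a]);
    }
    double gap = (double)(j + 1) / n - hy;
    if (gap > worst) worst = gap;
  }
  return worst;
}

// Dip statistic: half the smallest achievable sup-norm distance between the
// empirical cdf and a unimodal cdf (convex below the mode, concave above,
// with an atom permitted at the mode). Minimizes, over all candidate mode
// locations (between points, or at a tied cluster which the modal atom then
// absorbs), the larger of the left-limb and right-limb deficiencies.
// [[Rcpp::export]]
double dip_stat_cpp(NumericVector xs) {
  int n = xs.size();
  if (n < 2) return 0.0;
  std::vector<double> x(xs.begin(), xs.end());
  std::sort(x.begin(), x.end());
  std::vector<int> hull;
  // eleft[i]: deficiency of points 1..i (prefix of size i); nondecreasing.
  std::vector<double> eleft(n + 1, 0.0);
  for (int i = 0; i <= n; ++i)
    eleft[i] = prefix_deficiency(x.data(), i, n, hull);
  // eright[j]: deficiency of points j..n (1-based); computed on mirrored data.
  std::vector<double> xr(n);
  for (int j = 0; j < n; ++j) xr[j] = -x[n - 1 - j];
  std::vector<double> eright(n + 2, 0.0);
  for (int i = 0; i <= n; ++i)
    eright[n - i + 1] = prefix_deficiency(xr.data(), i, n, hull);
  double best = R_PosInf;
  // mode between points k and k+1 (no atom)
  for (int k = 0; k <= n; ++k) {
    double e = std::max(eleft[k], eright[k + 1]);
    if (e < best) best = e;
  }
  // mode at a tied cluster: the modal atom absorbs the whole cluster
  int lo = 0;  // 0-based start of current cluster
  for (int j = 1; j <= n; ++j) {
    if (j == n || x[j] != x[j - 1]) {
      // cluster is 0-based [lo, j-1]; left limb has `lo` points, right limb
      // starts at 1-based index j+1
      double e = std::max(eleft[lo], eright[j + 1]);
      if (e < best) best = e;
      lo = j;
    }
  }
  return 0.5 * best;
}
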