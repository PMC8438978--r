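#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Regression random-forest variable importance for one target gene.
//
// Trees are CART regression trees grown on bootstrap samples (optional),
// with `mtry` candidate predictors drawn uniformly at each node and the best
// split chosen by impurity (sum of squared deviations) reduction. Ties are
// broken in favour of the candidate drawn first. Importance of predictor j
// is the impurity reduction summed over all nodes splitting on j, summed
// over trees, divided by (ntrees * n). On a unit-variance target the
// importances of all predictors therefore sum to at most ~1 per target.
//
// Uses R's RNG so results are reproducible via set.seed().

namespace {

struct Forest {
  const NumericMatrix &X; // n x p
  const NumericVector &y; // length n (values for the *current* sample ids)
  int n, p, mtry, maxdepth;
  std::vector<double> imp;
  std::vector<int> cand;     // scratch for candidate sampling
  std::vector<int> buf;      // scratch for sorting node members

  Forest(const NumericMatrix &X_, const NumericVector &y_, int mtry_,
         int maxdepth_)
      : X(X_), y(y_), n(X_.nrow()), p(X_.ncol()), mtry(mtry_),
        maxdepth(maxdepth_), imp(p, 0.0), cand(p) {
    for (int j = 0; j < p; ++j) cand[j] = j;
  }

  // impurity = sum (y - mean)^2 over the node members
  double impurity(const std::vector<int> &idx) const {
    double s = 0.0, ss = 0.0;
    for (int i : idx) { s += y[i]; ss += y[i] * y[i]; }
    return ss - s * s / idx.size();
  }

  void grow(std::vector<int> &idx, int depth) {
    const int N = (int)idx.size();
    if (N < 2) return;
    if (maxdepth > 0 && depth >= maxdepth) return;
    double imp_node = impurity(idx);
    if (imp_node <= 1e-12 * N) return;

    // partial Fisher-Yates: first mtry entries of cand are the candidates
    int k = std::min(mtry, p);
    for (int j = 0; j < k; ++j) {
      int r = j + (int)(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(cand[j], cand[r]);
    }

    double best_red = 0.0, best_cut = 0.0;
    int best_j = -1;
    buf = idx;
    for (int cj = 0; cj < k; ++cj) {
      int j = cand[cj];
      std::sort(buf.begin(), buf.end(), [&](int a, int b) {
        return X(a, j) < X(b, j);
      });
      double sl = 0.0, ssl = 0.0;
      double st = 0.0, sst = 0.0;
      for (int i : buf) { st += y[i]; sst += y[i] * y[i]; }
      for (int t = 0; t < N - 1; ++t) {
        int i = buf[t];
        sl += y[i]; ssl += y[i] * y[i];
        if (X(buf[t], j) >= X(buf[t + 1], j)) continue; // no cut between ties
        int Nl = t + 1, Nr = N - Nl;
        double imp_l = ssl - sl * sl / Nl;
        double sr = st - sl, ssr = sst - ssl;
        double imp_r = ssr - sr * sr / Nr;
        double red = imp_node - imp_l - imp_r;
        if (red > best_red) { // strict: earlier candidate wins ties
          best_red = red;
          best_j = j;
          best_cut = 0.5 * (X(buf[t], j) + X(buf[t + 1], j));
        }
      }
    }
    if (best_j < 0) return;
    imp[best_j] += best_red;

    std::vector<int> left, right;
    left.reserve(N); right.reserve(N);
    for (int i : idx) {
      if (X(i, best_j) <= best_cut) left.push_back(i);
      else right.push_back(i);
    }
    if (left.empty() || right.empty()) return; // numerical guard
    grow(left, depth + 1);
    grow(right, depth + 1);
  }
};

} // namespace

// [[Rcpp::export(name = ".rf_importance")]]
NumericVector rf_importance(NumericMatrix X, NumericVector y, int ntrees,
                            int mtry, int maxdepth, bool bootstrap) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (n < 3) stop("at least 3 observations are required");
  if (p < 1) stop("at least 1 predictor is required");
  if (ntrees < 1) stop("ntrees must be >= 1");

  Forest f(X, y, mtry, maxdepth);
  std::vector<int> idx(n);
  for (int t = 0; t < ntrees; ++t) {
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int r = (int)(unif_rand() * n);
        idx[i] = r >= n ? n - 1 : r;
      }
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    std::vector<int> root = idx;
    f.grow(root, 0);
  }
  NumericVector out(p);
  const double denom = (double)ntrees * (double)n;
  for (int j = 0; j < p; ++j) out[j] = f.imp[j] / denom;
  return out;
}
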