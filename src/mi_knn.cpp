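#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (algorithm 1) mutual information between
// two continuous variables, in nats. Chebyshev (max) metric in the joint
// space; strict inequality for the marginal counts.
// [[Rcpp::export]]
double ksg_mi_nats(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (y.size() != n) stop("length mismatch");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");
  std::vector<double> d(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = std::fabs(x[j] - x[i]);
      double dy = std::fabs(y[j] - y[i]);
      d[m++] = dx > dy ? dx : dy;
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.begin() + m);
    double eps = d[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(x[j] - x[i]) < eps) ++nx;
      if (std::fabs(y[j] - y[i]) < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// Ross estimator for mutual information between a discrete and a
// continuous variable, in nats. For each point, the distance to its k-th
// nearest neighbor within its own class defines a radius; m counts all
// points (any class) within that radius (inclusive), excluding self.
// [[Rcpp::export]]
double ross_mi_nats(IntegerVector d, NumericVector y, int k) {
  int n = d.size();
  if (y.size() != n) stop("length mismatch");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");
  // class sizes
  std::map<int, int> csize;
  for (int i = 0; i < n; ++i) csize[d[i]]++;
  for (std::map<int, int>::iterator it = csize.begin();
       it != csize.end(); ++it)
    if (it->second < 2)
      stop("every discrete class needs at least 2 points");
  std::vector<double> dist;
  dist.reserve(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int Nc = csize[d[i]];
    int ki = std::min(k, Nc - 1);
    dist.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && d[j] == d[i])
        dist.push_back(std::fabs(y[j] - y[i]));
    std::nth_element(dist.begin(), dist.begin() + (ki - 1), dist.end());
    double eps = dist[ki - 1];
    int m = 0;
    for (int j = 0; j < n; ++j)
      if (j != i && std::fabs(y[j] - y[i]) <= eps) ++m;
    acc += R::digamma((double)ki) - R::digamma((double)Nc)
         - R::digamma((double)m);
  }
  return R::digamma((double)n) + acc / n;
}
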