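#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Kraskov-Stuebgen-Grassberger mutual information (algorithm 1) for two
// dx- and dy-dimensional streams, Chebyshev (max) metric, brute-force
// neighbour search. I = psi(k) + psi(N) - <psi(n_x + 1) + psi(n_y + 1)>.
// One fused O(n^2) pass per point: marginal distances are computed once,
// the joint distance is their max, and the marginal neighbour counts are
// taken against the k-th joint distance.
// [[Rcpp::export]]
double ksg_mi_cpp(NumericMatrix x, NumericMatrix y, int k) {
  const int n = x.nrow();
  const int dx = x.ncol(), dy = y.ncol();
  if (y.nrow() != n) stop("frame-count mismatch");
  if (k < 1 || k >= n) stop("k out of range");

  // column-contiguous copies for cache-friendly row access
  std::vector<double> xr((size_t)n * dx), yr((size_t)n * dy);
  for (int a = 0; a < dx; ++a)
    for (int i = 0; i < n; ++i) xr[(size_t)i * dx + a] = x(i, a);
  for (int a = 0; a < dy; ++a)
    for (int i = 0; i < n; ++i) yr[(size_t)i * dy + a] = y(i, a);

  std::vector<double> mdx(n), mdy(n), joint(n);
  double acc = 0.0;

  for (int i = 0; i < n; ++i) {
    const double* xi = &xr[(size_t)i * dx];
    const double* yi = &yr[(size_t)i * dy];
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double* xj = &xr[(size_t)j * dx];
      double a = 0.0;
      for (int c = 0; c < dx; ++c) {
        double t = std::fabs(xi[c] - xj[c]);
        if (t > a) a = t;
      }
      const double* yj = &yr[(size_t)j * dy];
      double b = 0.0;
      for (int c = 0; c < dy; ++c) {
        double t = std::fabs(yi[c] - yj[c]);
        if (t > b) b = t;
      }
      mdx[m] = a; mdy[m] = b; joint[m] = a > b ? a : b;
      ++m;
    }
    std::vector<double> tmp(joint.begin(), joint.begin() + m);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < m; ++j) {
      if (mdx[j] < eps) ++nx;
      if (mdy[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}
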